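# Default segmentation of the 60-column bHLH motif frame (1-based closed
# column intervals): a ~15-residue basic region followed by helix 1, the
# loop and helix 2.
frame_length: 60
basic: [1, 15]
helix1: [16, 30]
loop: [31, 44]
helix2: [45, 60]
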