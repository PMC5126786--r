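# Motif footprints, intron classification and intron statistics.

single_exon_model <- function(len_codons = 100, offset = 500L) {
  gene_model("g", "s", "+",
             tibble::tibble(start = offset,
                            end = offset + 3L * len_codons))
}

test_that("motif footprints map protein intervals onto the genome", {
  m <- single_exon_model(100, 500L)
  fp <- motif_genomic_footprint(m, c(10L, 70L))
  expect_equal(nrow(fp), 1)
  expect_equal(fp$start, 500L + 30L)
  expect_equal(fp$end, 500L + 30L + 180L)

  expect_error(motif_genomic_footprint(m, c(50L, 120L)), "outside")

  # two-exon gene with the intron inside the motif
  m2 <- gene_model("g2", "s", "+",
                   tibble::tibble(start = c(0L, 200L),
                                  end = c(90L, 410L)))
  fp2 <- motif_genomic_footprint(m2, c(20L, 80L))
  expect_equal(nrow(fp2), 2)
  expect_equal(sum(fp2$end - fp2$start), 180L)
})

test_that("minus-strand footprints decrease and round-trip translation", {
  withr::with_seed(51, {
    prot <- rand_protein(60)
    cds <- bhlhscan:::back_translate(prot)
    intron <- paste(sample(c("A", "C", "G", "T"), 70, TRUE), collapse = "")
    construct <- paste0(substr(cds, 1, 75), intron, substr(cds, 76, 180))
    rc <- bhlhscan:::revcomp(construct)
    scaf <- paste0(strrep("AC", 100), rc, strrep("GT", 100))
  })
  glen <- nchar(construct)
  # transcription-space exons [0,75) and [75+70, glen)
  ex <- tibble::tibble(start = c(200L + glen - 75L, 200L),
                       end = c(200L + glen, 200L + glen - 145L))
  m <- gene_model("gm", "s", "-", ex)
  expect_equal(model_protein(m, scaf), prot)
  fp <- motif_genomic_footprint(m, c(0L, 60L))
  expect_true(all(diff(fp$start) < 0))
  expect_equal(sum(fp$end - fp$start), 180L)
})

test_that("introns are classified by phase and motif region", {
  m0 <- single_exon_model()
  expect_equal(nrow(classify_introns(m0, c(10L, 70L))), 0)

  # intron interrupting codon 45 (phase 1), motif residues [20, 80):
  # motif column 45 - 20 + 1 = 26 -> helix1 under the default scheme
  m1 <- gene_model("g", "s", "+",
                   tibble::tibble(start = c(0L, 1000L),
                                  end = c(136L, 1000L + 300L - 136L)))
  rec <- classify_introns(m1, c(20L, 80L))
  expect_equal(rec$phase, 1L)
  expect_equal(rec$length, 864L)
  expect_equal(rec$location, "helix1")

  # same split point, no motif overlap -> outside_motif
  rec2 <- classify_introns(m1, c(50L, 99L))
  expect_equal(rec2$location, "outside_motif")

  # intron exactly between codons belongs to the following codon's region
  m3 <- gene_model("g", "s", "+",
                   tibble::tibble(start = c(0L, 500L),
                                  end = c(60L, 740L)))
  rec3 <- classify_introns(m3, c(20L, 80L))
  expect_equal(rec3$phase, 0L)
  # following codon = 20 -> motif column 1 -> basic
  expect_equal(rec3$location, "basic")

  expect_error(gene_model("g", "s", "+",
                          tibble::tibble(start = c(0L, 30L),
                                         end = c(60L, 90L))), "overlap")
})

test_that("intron classification is invariant under strand flipping", {
  withr::with_seed(52, {
    for (trial in 1:5) {
      b <- mini_bundle(seed = 60 + trial)
      models <- b$genome$models
      sc <- b$genome$scaffolds
      for (i in seq_len(nrow(models))) {
        m <- models[i, ]
        tr <- b$candidates[match(m$gene_id, b$candidates$id), ]
        motif <- if (!m$is_decoy) c(tr$motif_start, tr$motif_end) else NULL
        rec <- classify_introns(m, motif)
        # flip the scaffold: reverse-complement coordinates
        L <- nchar(sc$seq[match(m$scaffold_id, sc$id)])
        ex <- m$exons[[1]]
        flipped <- gene_model(m$gene_id, m$scaffold_id,
                              if (m$strand == "+") "-" else "+",
                              tibble::tibble(start = L - ex$end,
                                             end = L - ex$start))
        rec2 <- classify_introns(flipped, motif)
        expect_equal(rec$location, rec2$location)
        expect_equal(rec$phase, rec2$phase)
        expect_equal(rec$length, rec2$length)
      }
    }
  })
})

test_that("intron summaries match direct arithmetic", {
  rec <- tibble::tibble(gene_id = c("a", "a", "b"), index = c(1L, 2L, 1L),
                        length = c(40L, 60L, 200L), phase = c(0L, 1L, 2L),
                        location = c("loop", "outside_motif", "helix2"))
  st <- summarize_introns(rec, n_genes = 3)
  expect_equal(st$n_intronless, 1)
  expect_equal(st$total_introns, 3)
  expect_equal(st$min_length, 40L)
  expect_equal(st$max_length, 200L)
  expect_equal(st$mean_length, 100L)
  expect_equal(st$mean_per_gene, 1.5)  # 3 introns / 2 intron-bearing genes
  expect_equal(summarize_introns(rec, 3, "all")$mean_per_gene, 1)
  expect_equal(st$in_loop, 1L)
  expect_equal(st$motif_introns, 2L)
  expect_equal(st$motif_interrupted_genes, 2L)

  z <- summarize_introns(rec[0, ], n_genes = 0)
  expect_equal(z$total_introns, 0)
  expect_equal(z$n_intronless, 0)
})

test_that("recovered intron structure equals the generator truth", {
  b <- mini_bundle(seed = 77)
  models <- b$genome$models
  # reclassify from the models and compare against the stored truth table
  rec <- purrr::map_dfr(seq_len(nrow(models)), function(i) {
    m <- models[i, ]
    tr <- b$candidates[match(m$gene_id, b$candidates$id), ]
    motif <- if (!m$is_decoy) c(tr$motif_start, tr$motif_end) else NULL
    classify_introns(m, motif)
  })
  expect_equal(rec, b$genome$truth_introns)
  # exon + intron lengths tile the gene span
  for (i in seq_len(nrow(models))) {
    ex <- models$exons[[i]]
    introns <- bhlhscan:::model_introns(models[i, ])
    expect_equal(sum(ex$end - ex$start) + sum(introns$length),
                 max(ex$end) - min(ex$start))
  }
})
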