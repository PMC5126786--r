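# Seeded synthetic-data generator: reference family sets, divergent
# candidate proteins, and genome scaffolds with planted multi-exon genes,
# each with a complete truth table. All randomness flows from the single
# configured seed.

#' Simulation configuration
#'
#' Defines the study conditions emulated by the generator: a set of
#' ortholog families sharing a ~60-residue domain, reference members in two
#' species, candidates diverged from the family ancestors, and genes
#' embedded in scaffolds with a broad (log-uniform) intron length
#' distribution.
#'
#' @param seed Mandatory integer seed.
#' @param n_families Number of ortholog families (>= 2).
#' @param species Reference species labels (one reference set each).
#' @param frame_length Domain length in residues.
#' @param family_divergence Expected substitutions/site from the shared
#'   root domain to each family ancestor (families are homologous copies of
#'   one domain, as in a real transcription-factor superfamily).
#' @param n_conserved_sites Number of domain columns placed under strong
#'   purifying selection (near-frozen across all families); these emulate
#'   the diagnostic conserved sites of the domain.
#' @param conserved_rate_factor Rate multiplier applied at conserved sites.
#' @param branch_rate Expected substitutions/site from a family ancestor to
#'   each reference member.
#' @param candidate_divergence Expected substitutions/site from the ancestor
#'   to a candidate.
#' @param insertion_prob Probability that a candidate carries one extra
#'   residue inside its domain.
#' @param n_candidates,n_decoys Planted true genes and non-domain decoy
#'   genes.
#' @param min_intron,max_intron Intron length bounds (log-uniform draw).
#' @param max_exons Exon count per gene drawn uniformly from 1..max_exons.
#' @param protein_flank Range of random flanking residues on each side of
#'   the domain.
#' @param genomic_flank Range of random scaffold sequence flanking each
#'   gene.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(seed, n_families = 8,
                              species = c("spA", "spB"),
                              frame_length = 60, family_divergence = 0.8,
                              n_conserved_sites = 19,
                              conserved_rate_factor = 0.02,
                              branch_rate = 0.05,
                              candidate_divergence = 0.25,
                              insertion_prob = 0.1,
                              n_candidates = 10, n_decoys = 3,
                              min_intron = 35, max_intron = 1e6,
                              max_exons = 6,
                              protein_flank = c(30, 80),
                              genomic_flank = c(2000, 10000)) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  stopifnot(n_families >= 2, length(species) >= 1, branch_rate >= 0,
            family_divergence >= 0, n_conserved_sites >= 0,
            n_conserved_sites <= frame_length, conserved_rate_factor >= 0,
            candidate_divergence >= 0, insertion_prob >= 0,
            min_intron >= 1, max_intron >= min_intron, max_exons >= 1)
  structure(as.list(environment()), class = "simulation_config")
}

# substitute each site independently with probability 1 - exp(-rate * f),
# where f is an optional per-site rate factor (purifying selection),
# replacing by a uniformly drawn different residue
mutate_seq <- function(seq, rate, site_factors = NULL) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  f <- site_factors %||% rep(1, length(ch))
  p <- 1 - exp(-rate * f)
  hit <- which(stats::runif(length(ch)) < p)
  for (i in hit) {
    ch[i] <- sample(setdiff(AA_ALPHABET, ch[i]), 1)
  }
  paste(ch, collapse = "")
}

random_protein <- function(n) paste(sample(AA_ALPHABET, n, replace = TRUE),
                                    collapse = "")

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

#' Simulate reference family sets
#'
#' Draws one root domain, designates `n_conserved_sites` columns as
#' near-frozen (strong purifying selection), evolves one family ancestor
#' per family from the root at `family_divergence`, and one member per
#' species from each ancestor along a star tree at `branch_rate`.
#' High-order groups are assigned cyclically over A, B, C so that every
#' group holds several families. The outgroup is sampled independently of
#' all families.
#'
#' @param cfg A [simulation_config()].
#' @return A list with `refsets` (one [reference_set()] per species, in
#'   `cfg$species` order), `root`, `conserved_columns`, `site_factors`,
#'   `ancestors` (named character), `outgroup_seq`, and `truth` (tibble of
#'   member id, species, family, group).
#' @export
simulate_reference_set <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  with_seed(cfg$seed, {
    fams <- sprintf("fam%02d", seq_len(cfg$n_families))
    groups <- rep(c("A", "B", "C"), length.out = cfg$n_families)
    root <- random_protein(cfg$frame_length)
    cons <- sort(sample.int(cfg$frame_length, cfg$n_conserved_sites))
    fac <- rep(1, cfg$frame_length)
    fac[cons] <- cfg$conserved_rate_factor
    ancestors <- stats::setNames(
      vapply(fams, function(f) mutate_seq(root, cfg$family_divergence, fac),
             character(1)), fams)
    members <- purrr::map_dfr(cfg$species, function(sp) {
      purrr::map_dfr(seq_along(fams), function(k) {
        tibble(id = paste0(sp, "_", fams[k]), species = sp,
               family = fams[k], group = groups[k],
               seq = mutate_seq(ancestors[[k]], cfg$branch_rate, fac))
      })
    })
    outgroup_seq <- random_protein(cfg$frame_length)
    refsets <- lapply(cfg$species, function(sp) {
      reference_set(members[members$species == sp, ],
                    outgroup_id = "outgroup", outgroup_seq = outgroup_seq,
                    label = sp)
    })
    names(refsets) <- cfg$species
    list(refsets = refsets, root = root, conserved_columns = cons,
         site_factors = fac, ancestors = ancestors,
         outgroup_seq = outgroup_seq,
         truth = members[, c("id", "species", "family", "group")])
  })
}

#' Evolve candidate proteins from family ancestors
#'
#' Each candidate descends from a uniformly chosen family ancestor at
#' `candidate_divergence`, optionally gains one extra residue inside the
#' domain, and is embedded between random flanking residues.
#'
#' @param refsim A [simulate_reference_set()] result.
#' @param cfg The same [simulation_config()].
#' @return A tibble: `id`, `family`, `seq` (full protein), `motif_start`,
#'   `motif_end` (0-based half-open residue coordinates of the planted
#'   domain), `has_insertion`.
#' @export
evolve_candidates <- function(refsim, cfg) {
  with_seed(cfg$seed + 1L, {
    fams <- names(refsim$ancestors)
    purrr::map_dfr(seq_len(cfg$n_candidates), function(i) {
      fam <- sample(fams, 1)
      motif <- mutate_seq(refsim$ancestors[[fam]],
                          cfg$candidate_divergence, refsim$site_factors)
      ins <- stats::runif(1) < cfg$insertion_prob
      if (ins) {
        pos <- sample(2:(nchar(motif) - 1), 1)
        motif <- paste0(substr(motif, 1, pos), sample(AA_ALPHABET, 1),
                        substr(motif, pos + 1, nchar(motif)))
      }
      nf1 <- sample(cfg$protein_flank[1]:cfg$protein_flank[2], 1)
      nf2 <- sample(cfg$protein_flank[1]:cfg$protein_flank[2], 1)
      tibble(id = sprintf("cand%02d", i), family = fam,
             seq = paste0(random_protein(nf1), motif, random_protein(nf2)),
             motif_start = nf1,
             motif_end = nf1 + nchar(motif),
             has_insertion = ins)
    })
  })
}

# reverse genetic-code table: residue -> codons (stops excluded)
codon_choices <- function() {
  gc <- gencode()
  split(names(gc), unname(gc))
}

back_translate <- function(protein) {
  tab <- codon_choices()
  ch <- strsplit(protein, "", fixed = TRUE)[[1]]
  paste(vapply(ch, function(a) {
    opts <- tab[[a]]
    if (length(opts) == 1) opts else sample(opts, 1)
  }, character(1)), collapse = "")
}

#' Plant genes on synthetic scaffolds
#'
#' Back-translates each candidate (and random decoy proteins), splits the
#' coding sequence into 1..`max_exons` exons at random codon boundaries,
#' draws intron lengths log-uniformly from
#' `[min_intron, max_intron]`, and plants each gene on its own scaffold on a
#' random strand between random flanking sequence.
#'
#' @param candidates An [evolve_candidates()] tibble.
#' @param cfg The same [simulation_config()].
#' @return A list with `scaffolds` (tibble `id`, `seq`), `models`
#'   (gene-model tibble with `is_decoy` and `family`), and `truth_introns`
#'   (intron records labelled by the motif region they interrupt).
#' @export
build_synthetic_genome <- function(candidates, cfg) {
  with_seed(cfg$seed + 2L, {
    genes <- dplyr::bind_rows(
      candidates[, c("id", "family", "seq", "motif_start", "motif_end")],
      purrr::map_dfr(seq_len(cfg$n_decoys), function(i) {
        tibble(id = sprintf("decoy%02d", i), family = NA_character_,
               seq = random_protein(sample(150:220, 1)),
               motif_start = NA_integer_, motif_end = NA_integer_)
      }))
    scaffolds <- list()
    models <- list()
    introns_truth <- list()
    for (i in seq_len(nrow(genes))) {
      g <- genes[i, ]
      cds <- paste0(back_translate(g$seq),
                    sample(c("TAA", "TAG", "TGA"), 1))
      n_codon <- nchar(cds) %/% 3
      n_exons <- sample.int(cfg$max_exons, 1)
      cuts <- if (n_exons > 1) {
        sort(sample(seq_len(n_codon - 1), n_exons - 1)) * 3
      } else integer(0)
      bounds <- c(0, cuts, nchar(cds))
      exon_seqs <- substring(cds, bounds[-length(bounds)] + 1,
                             bounds[-1])
      intron_lens <- if (n_exons > 1) {
        as.integer(round(10^stats::runif(n_exons - 1,
                                         log10(cfg$min_intron),
                                         log10(cfg$max_intron))))
      } else integer(0)
      intron_seqs <- vapply(intron_lens, random_dna, character(1))
      # assemble the gene in transcription orientation and record
      # transcription-space exon positions
      pieces <- character(0)
      pos <- 0
      ex_pos <- matrix(0L, nrow = n_exons, ncol = 2)
      for (k in seq_len(n_exons)) {
        ex_pos[k, ] <- c(pos, pos + nchar(exon_seqs[k]))
        pieces <- c(pieces, exon_seqs[k])
        pos <- pos + nchar(exon_seqs[k])
        if (k < n_exons) {
          pieces <- c(pieces, intron_seqs[k])
          pos <- pos + nchar(intron_seqs[k])
        }
      }
      construct <- paste(pieces, collapse = "")
      glen <- nchar(construct)
      strand <- sample(c("+", "-"), 1)
      fl <- sample(cfg$genomic_flank[1]:cfg$genomic_flank[2], 1)
      fr <- sample(cfg$genomic_flank[1]:cfg$genomic_flank[2], 1)
      placed <- if (strand == "+") construct else revcomp(construct)
      scaffold_id <- sprintf("scf%03d", i)
      scaffolds[[i]] <- tibble(id = scaffold_id,
                               seq = paste0(random_dna(fl), placed,
                                            random_dna(fr)))
      exons <- if (strand == "+") {
        tibble(start = fl + ex_pos[, 1], end = fl + ex_pos[, 2])
      } else {
        tibble(start = fl + glen - ex_pos[, 2],
               end = fl + glen - ex_pos[, 1])
      }
      m <- gene_model(g$id, scaffold_id, strand, exons)
      m$is_decoy <- is.na(g$family)
      m$family <- g$family
      models[[i]] <- m
      motif <- if (!is.na(g$motif_start)) c(g$motif_start, g$motif_end)
               else NULL
      introns_truth[[i]] <- classify_introns(m, motif)
    }
    list(scaffolds = dplyr::bind_rows(scaffolds),
         models = dplyr::bind_rows(models),
         truth_introns = dplyr::bind_rows(introns_truth))
  })
}

#' Generate a complete synthetic study bundle
#'
#' Convenience wrapper chaining [simulate_reference_set()],
#' [evolve_candidates()] and [build_synthetic_genome()].
#'
#' @param cfg A [simulation_config()].
#' @return A list with `cfg`, `refsim`, `candidates`, `genome`.
#' @export
simulate_bundle <- function(cfg) {
  refsim <- simulate_reference_set(cfg)
  candidates <- evolve_candidates(refsim, cfg)
  genome <- build_synthetic_genome(candidates, cfg)
  list(cfg = cfg, refsim = refsim, candidates = candidates,
       genome = genome)
}
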