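# Independent oracles and shared fixtures for the test suite.

AA <- bhlhscan:::AA_ALPHABET

msa <- function(id, aligned) bhlhscan:::new_msa(id, aligned)

# identity scoring scheme over the 20-letter alphabet
identity_scheme <- function(match = 1, mismatch = 0, open = 1, ext = 1) {
  m <- matrix(mismatch, 20, 20, dimnames = list(AA, AA))
  diag(m) <- match
  scoring_scheme(m, gap_open = open, gap_ext = ext)
}

rand_protein <- function(n, alphabet = AA) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# ---- brute-force global alignment oracle ------------------------------------
# enumerate every global alignment path (moves D = both, U = consume a,
# L = consume b) and score each path independently; gap of length k costs
# open + (k - 1) * ext
brute_global_score <- function(a, b, scoring) {
  na <- nchar(a); nb <- nchar(b)
  ai <- if (na) bhlhscan:::aa_encode(a) else integer(0)
  bi <- if (nb) bhlhscan:::aa_encode(b) else integer(0)
  paths <- list()
  walk <- function(i, j, moves) {
    if (i == na && j == nb) {
      paths[[length(paths) + 1L]] <<- moves
      return(invisible())
    }
    if (i < na && j < nb) walk(i + 1, j + 1, c(moves, "D"))
    if (i < na) walk(i + 1, j, c(moves, "U"))
    if (j < nb) walk(i, j + 1, c(moves, "L"))
  }
  walk(0, 0, character(0))
  score_path <- function(mv) {
    s <- 0; i <- 0; j <- 0; run <- ""
    for (m in mv) {
      if (m == "D") {
        i <- i + 1; j <- j + 1
        s <- s + scoring$matrix[ai[i], bi[j]]
        run <- ""
      } else {
        s <- s - if (run == m) scoring$gap_ext else scoring$gap_open
        run <- m
        if (m == "U") i <- i + 1 else j <- j + 1
      }
    }
    s
  }
  max(vapply(paths, score_path, numeric(1)))
}

# ---- slow local-alignment oracle --------------------------------------------
# plain dense Smith-Waterman (score of the best local alignment), written
# independently of the scanning implementation
slow_local_best <- function(qidx, sidx, smat, open, ext) {
  n <- length(qidx); m <- length(sidx)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)
  F_ <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(H[i, j - 1] - open, E[i, j - 1] - ext)
      F_[i, j] <- max(H[i - 1, j] - open, F_[i - 1, j] - ext)
      H[i, j] <- max(0, H[i - 1, j - 1] + smat[qidx[i - 1], sidx[j - 1]],
                     E[i, j], F_[i, j])
      best <- max(best, H[i, j])
    }
  }
  best
}

# ---- sequence evolution on a tree (strong-signal alignments) ----------------
evolve_on_tree <- function(n = 6, len = 60, rate = 0.15) {
  tr <- ape::rtree(n)
  seqs <- character(max(tr$edge))
  seqs[n + 1] <- rand_protein(len)
  for (k in order(tr$edge[, 1])) {
    p <- tr$edge[k, 1]; ch <- tr$edge[k, 2]
    seqs[ch] <- bhlhscan:::mutate_seq(seqs[p], rate)
  }
  list(tree = tr, seqs = stats::setNames(seqs[1:n], tr$tip.label))
}

# ---- cached end-to-end synthetic run ----------------------------------------
# the default-condition bundle is expensive; build it once per test session
.e2e_cache <- new.env(parent = emptyenv())

e2e_run <- function() {
  if (!exists("res", envir = .e2e_cache)) {
    cfg <- simulation_config(seed = 2026)
    bundle <- simulate_bundle(cfg)
    refs <- bundle$refsim$refsets
    ref_seqs <- do.call(c, lapply(refs, function(r)
      stats::setNames(r$members$seq, r$members$id)))
    stbl <- site_table_from_motifs(unname(ref_seqs))
    t0 <- Sys.time()
    survey <- run_survey(bundle$genome$scaffolds, ref_seqs,
                         bundle$genome$models, site_table = stbl)
    classification <- run_classification(survey_motifs(survey), refs,
                                         reps = 200, seed = 2027)
    runtime <- as.numeric(Sys.time() - t0, units = "secs")
    assign("res", list(cfg = cfg, bundle = bundle, survey = survey,
                       classification = classification,
                       site_table = stbl, runtime = runtime),
           envir = .e2e_cache)
  }
  get("res", envir = .e2e_cache)
}

# small, fast synthetic bundle for unit-level pipeline tests
mini_bundle <- function(seed = 11) {
  cfg <- simulation_config(seed = seed, n_families = 4, n_candidates = 4,
                           n_decoys = 1, max_intron = 3000,
                           genomic_flank = c(500, 2000))
  simulate_bundle(cfg)
}

# score one explicit alignment path (moves D/U/L) under the affine scheme
score_move_path <- function(mv, ai, bi, scoring) {
  s <- 0; i <- 0; j <- 0; run <- ""
  for (m in mv) {
    if (m == "D") {
      i <- i + 1; j <- j + 1
      s <- s + scoring$matrix[ai[i], bi[j]]
      run <- ""
    } else {
      s <- s - if (run == m) scoring$gap_ext else scoring$gap_open
      run <- m
      if (m == "U") i <- i + 1 else j <- j + 1
    }
  }
  s
}

# a uniformly random valid global alignment of a and b, scored independently
brute_random_alignment_score <- function(a, b, scoring) {
  na <- nchar(a); nb <- nchar(b)
  ai <- bhlhscan:::aa_encode(a); bi <- bhlhscan:::aa_encode(b)
  i <- 0; j <- 0; mv <- character(0)
  while (i < na || j < nb) {
    opts <- c(if (i < na && j < nb) "D", if (i < na) "U", if (j < nb) "L")
    m <- sample(opts, 1)
    mv <- c(mv, m)
    if (m != "L") i <- i + 1
    if (m != "U") j <- j + 1
  }
  score_move_path(mv, ai, bi, scoring)
}

# score of the pairwise alignment induced by two gapped rows
projected_pair_score <- function(ri, rj, scoring) {
  s <- 0; run <- ""
  for (k in seq_along(ri)) {
    if (ri[k] == "-" && rj[k] == "-") next
    if (ri[k] != "-" && rj[k] != "-") {
      s <- s + scoring$matrix[ri[k], rj[k]]
      run <- ""
    } else {
      side <- if (ri[k] == "-") "i" else "j"
      s <- s - if (run == side) scoring$gap_ext else scoring$gap_open
      run <- side
    }
  }
  s
}

# mean substitution score of a gapped row against a profile matrix, with
# affine penalties for its gap runs (used for relative comparisons only)
profile_row_score <- function(profmat, row, scoring) {
  ch <- strsplit(row, "")[[1]]
  s <- 0; in_gap <- FALSE
  for (k in seq_along(ch)) {
    if (ch[k] == "-") {
      s <- s - if (in_gap) scoring$gap_ext else scoring$gap_open
      in_gap <- TRUE
    } else {
      in_gap <- FALSE
      col <- profmat[, k]
      col <- col[col != "-"]
      if (length(col)) s <- s + mean(scoring$matrix[ch[k], col])
    }
  }
  s
}
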