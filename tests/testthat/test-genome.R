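# Six-frame translation, translated local search, locus building,
# deduplication and the filter cascade.

test_that("six-frame translation matches the codon table and Biostrings", {
  fr <- six_frame_translate("ATGGCC")
  expect_equal(fr$protein[fr$strand == "+" & fr$frame == 0], "MA")
  # reverse strand of GGCCAT reads ATGGCC
  fr2 <- six_frame_translate("GGCCAT")
  expect_equal(fr2$protein[fr2$strand == "-" & fr2$frame == 0], "MA")

  expect_error(six_frame_translate(""), "empty")
  expect_error(six_frame_translate("ACGU"), "outside")

  withr::with_seed(41, {
    s <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
  })
  fr3 <- six_frame_translate(s)
  for (f in 0:2) {
    ref <- as.character(Biostrings::translate(
      Biostrings::subseq(Biostrings::DNAString(s), f + 1,
                         f + 3 * ((300 - f) %/% 3)),
      if.fuzzy.codon = "X"))
    expect_equal(fr3$protein[fr3$strand == "+" & fr3$frame == f], ref)
  }
  # N-containing codons translate to X
  expect_equal(six_frame_translate("ATGNNA")$protein[1], "MX")
})

test_that("translated search finds exact encodings at the exact score", {
  withr::with_seed(42, {
    q <- rand_protein(40)
    cds <- bhlhscan:::back_translate(q)
    scaf <- paste0(rand_protein(0),
                   paste(sample(c("A", "C", "G", "T"), 901, TRUE),
                         collapse = ""),
                   cds,
                   paste(sample(c("A", "C", "G", "T"), 600, TRUE),
                         collapse = ""))
  })
  sc <- scoring_scheme()
  hits <- translated_local_search(q, c(s = scaf), sc, min_score = 60)
  top <- hits[which.max(hits$score), ]
  qidx <- bhlhscan:::aa_encode(q)
  expect_equal(top$score, sum(sc$matrix[cbind(qidx, qidx)]))
  expect_equal(top$start, 901L)
  expect_equal(top$end, 901L + 120L)

  expect_error(translated_local_search("MKV", c(s = scaf)), ">= 10")
  expect_error(translated_local_search(q, c(s = scaf),
                                       scoring_scheme(gap_open = 0)),
               "positive")
  # all-N scaffold: nothing alignable
  expect_equal(nrow(translated_local_search(q, c(n = strrep("N", 500)))), 0)
})

test_that("search hit scores equal a slow dense Smith-Waterman", {
  sc <- scoring_scheme()
  withr::with_seed(43, {
    for (trial in 1:8) {
      q <- rand_protein(15)
      scaf <- paste(sample(c("A", "C", "G", "T"), 240, TRUE), collapse = "")
      hits <- translated_local_search(q, c(s = scaf), sc, min_score = 1)
      qidx <- bhlhscan:::aa_encode(q)
      f6 <- six_frame_translate(scaf)
      best_ref <- 0
      for (fr in seq_len(6)) {
        subj <- bhlhscan:::aa_encode(f6$protein[fr], allow_x = TRUE)
        # alignments cannot cross stop codons: score each clean segment
        segs <- split(subj, cumsum(subj == 0))
        for (sg in segs) {
          sg <- sg[sg > 0]
          if (length(sg) < 2) next
          best_ref <- max(best_ref, slow_local_best(qidx, sg, sc$matrix,
                                                    sc$gap_open, sc$gap_ext))
        }
      }
      best_mine <- if (nrow(hits)) max(hits$score) else 0
      if (best_ref >= 1) expect_equal(best_mine, best_ref)
      else expect_equal(best_mine, 0)
    }
  })
})

test_that("hit extension clamps, merges and contains its hits", {
  hits <- tibble::tibble(scaffold_id = "s", strand = "+", frame = 0,
                         start = 50000L, end = 50300L, q_start = 0L,
                         q_end = 100L, score = 500, evalue_proxy = 0,
                         query_id = "q")
  loci <- extend_and_merge(hits, flank = 10000,
                           scaffold_lengths = c(s = 200000L))
  expect_equal(loci$start, 40000L)
  expect_equal(loci$end, 60300L)

  h0 <- hits; h0$start <- 0L; h0$end <- 300L
  l0 <- extend_and_merge(h0, 10000, c(s = 200000L))
  expect_equal(l0$start, 0L)
  expect_equal(l0$end, 10300L)

  # two hits 5 kb apart merge under a 10 kb flank; union verified by IRanges
  h2 <- dplyr::bind_rows(hits, dplyr::mutate(hits, start = 55300L,
                                             end = 55600L))
  l2 <- extend_and_merge(h2, 10000, c(s = 200000L))
  expect_equal(nrow(l2), 1)
  ir <- IRanges::reduce(IRanges::IRanges(c(40001, 45301), c(60300, 65600)))
  expect_equal(l2$start, IRanges::start(ir) - 1L)
  expect_equal(l2$end, IRanges::end(ir))
  expect_equal(l2$n_hits, 2L)

  expect_error(extend_and_merge(hits, 100, c(other = 10L)),
               "unknown scaffold")
  # loci are pairwise disjoint per scaffold
  withr::with_seed(44, {
    hr <- tibble::tibble(scaffold_id = "s", strand = "+", frame = 0,
                         start = sort(sample.int(150000, 20)),
                         q_start = 0L, q_end = 10L, score = 1,
                         evalue_proxy = 0, query_id = "q")
    hr$end <- hr$start + 300L
    lr <- extend_and_merge(hr, 3000, c(s = 200000L))
    expect_true(all(lr$start[-1] > lr$end[-nrow(lr)]))
    expect_true(all(vapply(seq_len(nrow(hr)), function(i)
      any(lr$start <= hr$start[i] & lr$end >= hr$end[i]), logical(1))))
  })
})

test_that("gene models validate, translate and write/read GFF3", {
  withr::with_seed(45, {
    prot <- rand_protein(50)
    cds <- bhlhscan:::back_translate(prot)
    intron <- paste(sample(c("A", "C", "G", "T"), 80, TRUE), collapse = "")
    scaf <- paste0(strrep("ACGT", 25), substr(cds, 1, 60), intron,
                   substr(cds, 61, 150), strrep("TTGA", 25))
  })
  m <- gene_model("g1", "s1", "+",
                  tibble::tibble(start = c(100L, 240L),
                                 end = c(160L, 330L)))
  expect_equal(model_protein(m, scaf), prot)

  expect_error(gene_model("g", "s", "+",
                          tibble::tibble(start = c(0L, 50L),
                                         end = c(60L, 100L))), "overlap")
  expect_error(gene_model("g", "s", "+",
                          tibble::tibble(start = 0L, end = 50L)),
               "divisible")

  tmp <- withr::local_tempfile(fileext = ".gff3")
  write_gene_models(m, tmp)
  back <- read_gene_models(tmp)
  expect_equal(back$gene_id, "g1")
  expect_equal(back$exons[[1]], m$exons[[1]])
})

test_that("deduplication keeps one representative and is idempotent", {
  mk <- function(id, start, end, strand = "+", frame = 0) {
    tibble::tibble(gene_id = id, scaffold_id = "s", strand = strand,
                   frame = frame,
                   exons = list(tibble::tibble(start = start, end = end)),
                   cds_len = sum(end - start))
  }
  two_same <- dplyr::bind_rows(mk("a", 0L, 300L), mk("b", 0L, 300L))
  dd <- deduplicate_candidates(two_same)
  expect_equal(nrow(dd$candidates), 1)
  expect_equal(dd$candidates$gene_id, "a") # full tie -> first candidate kept
  expect_equal(dd$audit$kept_as, "a")

  diff_strand <- dplyr::bind_rows(mk("a", 0L, 300L),
                                  mk("b", 0L, 300L, strand = "-"))
  expect_equal(nrow(deduplicate_candidates(diff_strand)$candidates), 2)

  # reciprocal overlap 0.5 under a 0.8 threshold -> both kept
  partial <- dplyr::bind_rows(mk("a", 0L, 300L), mk("b", 150L, 450L))
  ro <- bhlhscan:::reciprocal_overlap(partial$exons[[1]], partial$exons[[2]])
  expect_equal(ro, c(0.5, 0.5))
  expect_equal(nrow(deduplicate_candidates(partial, 0.8)$candidates), 2)

  again <- deduplicate_candidates(dd$candidates)
  expect_equal(again$candidates, dd$candidates)
  expect_equal(nrow(again$audit), 0)
})

test_that("the filter cascade audits every decision", {
  b <- mini_bundle()
  refs <- do.call(c, lapply(b$refsim$refsets, function(r)
    stats::setNames(r$members$seq, r$members$id)))
  prof <- build_motif_profile(unname(refs))
  stbl <- site_table_from_motifs(unname(refs))

  cands <- tibble::tibble(
    gene_id = c("true1", "junk"),
    protein = c(b$candidates$seq[1], paste(rep("G", 150), collapse = "")))
  res <- candidate_filter_cascade(cands, prof, site_table = stbl)
  expect_equal(res$accepted$gene_id, "true1")
  junk_audit <- res$audit[res$audit$gene_id == "junk", ]
  expect_false(any(junk_audit$pass))
  expect_equal(junk_audit$reason[1], "no_motif")

  empty <- candidate_filter_cascade(cands[0, ], prof, site_table = stbl)
  expect_equal(nrow(empty$accepted), 0)
  expect_equal(nrow(empty$audit), 0)
})
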