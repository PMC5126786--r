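# Domain detection, conserved-site validation and region segmentation.

make_profile <- function(seed = 5, n = 4, len = 60, rate = 0.05) {
  withr::with_seed(seed, {
    anc <- rand_protein(len)
    motifs <- c(anc, vapply(seq_len(n - 1), function(i)
      bhlhscan:::mutate_seq(anc, rate), character(1)))
    list(profile = build_motif_profile(motifs), motifs = motifs)
  })
}

test_that("conserved-site checking counts matches exactly", {
  tbl <- conserved_site_table(
    tibble::tibble(column = c(2L, 5L, 9L), allowed = c("KR", "E", "LIV")),
    min_matches = 2)
  row_all <- paste(rep("A", 10), collapse = "")
  substr(row_all, 2, 2) <- "K"; substr(row_all, 5, 5) <- "E"
  substr(row_all, 9, 9) <- "V"
  res <- check_conserved_sites(row_all, tbl, frame_length = 10)
  expect_equal(res$matches, 3)
  expect_true(res$pass)
  expect_equal(res$matched_sites, c(2L, 5L, 9L))

  gaps <- strrep("-", 10)
  res0 <- check_conserved_sites(gaps, tbl, frame_length = 10)
  expect_equal(res0$matches, 0)
  expect_false(res0$pass)

  expect_error(check_conserved_sites("AAA", tbl, frame_length = 10),
               "frame length")
})

test_that("conserved-site matching equals an independent per-column scan", {
  withr::with_seed(42, {
    for (trial in 1:10) {
      cols <- sort(sample.int(60, 19))
      tbl <- conserved_site_table(
        tibble::tibble(column = cols,
                       allowed = vapply(cols, function(i)
                         paste(sample(AA, sample(1:4, 1)), collapse = ""),
                         character(1))),
        min_matches = 9)
      row <- rand_protein(60)
      ch <- strsplit(row, "")[[1]]
      manual <- sum(mapply(function(cc, al)
        ch[cc] %in% strsplit(al, "")[[1]], tbl$column, tbl$allowed))
      expect_equal(check_conserved_sites(row, tbl)$matches, manual)
    }
  })
})

test_that("a planted consensus motif is found at the planted offset", {
  p <- make_profile()
  stbl <- site_table_from_motifs(p$motifs)
  withr::with_seed(7, {
    prot <- paste0(rand_protein(25), p$profile$consensus, rand_protein(10))
    h <- scan_protein(prot, p$profile, site_table = stbl)
    expect_equal(nrow(h), 1)
    expect_equal(h$start, 25L)
    expect_equal(h$end, 85L)
    expect_true(h$pass)

    # short protein: no hits, not an error
    expect_equal(nrow(scan_protein(rand_protein(10), p$profile,
                                   site_table = stbl)), 0)

    # two planted copies -> two non-overlapping hits, sorted by start
    prot2 <- paste0(rand_protein(20), p$profile$consensus, rand_protein(50),
                    p$profile$consensus, rand_protein(10))
    h2 <- scan_protein(prot2, p$profile, site_table = stbl)
    expect_equal(nrow(h2), 2)
    expect_equal(h2$start, c(20L, 130L))
    expect_true(h2$end[1] <= h2$start[2])
  })
  expect_error(scan_protein("ACDB!", p$profile), "invalid residue")
})

test_that("scanning is deterministic and monotone in min_matches", {
  p <- make_profile(seed = 8)
  withr::with_seed(9, {
    prot <- paste0(rand_protein(30), bhlhscan:::mutate_seq(p$motifs[1], 0.2),
                   rand_protein(20))
  })
  stbl <- site_table_from_motifs(p$motifs)
  h1 <- scan_protein(prot, p$profile, site_table = stbl)
  h2 <- scan_protein(prot, p$profile, site_table = stbl)
  expect_identical(h1, h2)

  passes <- vapply(1:19, function(mm) {
    st <- site_table_from_motifs(p$motifs, min_matches = mm)
    sum(scan_protein(prot, p$profile, site_table = st)$pass)
  }, numeric(1))
  expect_true(all(diff(passes) <= 0))
})

test_that("planted motifs with up to 20% corruption are always recovered", {
  p <- make_profile(seed = 10)
  stbl <- site_table_from_motifs(p$motifs, min_matches = 9)
  withr::with_seed(11, {
    for (trial in 1:20) {
      motif <- bhlhscan:::mutate_seq(p$motifs[1], 0.2)
      off <- sample(10:60, 1)
      prot <- paste0(rand_protein(off), motif, rand_protein(sample(10:40, 1)))
      h <- scan_protein(prot, p$profile, site_table = stbl)
      h <- h[h$pass, ]
      expect_equal(nrow(h), 1)
      expect_equal(h$start, off)
    }
  })
})

test_that("region segmentation labels complete, missing and inserted regions", {
  p <- make_profile(seed = 12)
  stbl <- site_table_from_motifs(p$motifs)
  scheme <- region_scheme()
  withr::with_seed(13, {
    prot <- paste0(rand_protein(20), p$profile$consensus, rand_protein(10))
  })
  h <- scan_protein(prot, p$profile, scheme, stbl)
  seg <- segment_regions(h[1, ], scheme)
  expect_equal(seg$region, c("basic", "helix1", "loop", "helix2"))
  expect_true(all(seg$status == "complete"))
  expect_equal(seg$res_start[1], 20L)
  expect_equal(seg$res_end[4], 80L)

  # basic region truncated away entirely -> missing
  withr::with_seed(14, {
    trunc <- paste0(rand_protein(15), substr(p$profile$consensus, 16, 60),
                    rand_protein(10))
  })
  ht <- scan_protein(trunc, p$profile, scheme, stbl, min_coverage = 0.5)
  segt <- segment_regions(ht[1, ], scheme)
  expect_equal(segt$status[segt$region == "basic"], "missing")
  expect_true(all(segt$status[segt$region != "basic"] == "complete"))

  # one extra residue anchored in the loop
  cons <- p$profile$consensus
  ins_at <- 37
  withr::with_seed(15, {
    withins <- paste0(rand_protein(12), substr(cons, 1, ins_at), "W",
                      substr(cons, ins_at + 1, 60), rand_protein(12))
  })
  hi <- scan_protein(withins, p$profile, scheme, stbl)
  ins <- hi$insertions[[1]]
  expect_equal(nrow(ins), 1)
  expect_equal(ins$residue, "W")
  segi <- segment_regions(hi[1, ], scheme)
  expect_equal(segi$n_insertions[segi$region == "loop"], 1L)
})

test_that("site tables and region schemes validate and load from files", {
  expect_error(conserved_site_table(
    tibble::tibble(column = c(3L, 2L), allowed = c("A", "C"))),
    "strictly increasing")
  expect_error(conserved_site_table(
    tibble::tibble(column = 1L, allowed = "")), "non-empty")
  expect_equal(nrow(default_site_table()), 19)

  expect_error(region_scheme(basic = c(1, 20), helix1 = c(16, 30)),
               "cover the frame")
  rs <- read_region_scheme(system.file("extdata", "region_scheme.yml",
                                       package = "bhlhscan"))
  expect_equal(rs$frame_length, 60)
  expect_equal(rs$boundaries$loop, c(31, 44))
})
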