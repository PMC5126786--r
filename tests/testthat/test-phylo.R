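# Distances, neighbor joining, Fitch parsimony, bootstrap supports,
# rooting and monophyly queries.

test_that("p-distances match arithmetic and a direct recount", {
  aln <- msa(c("a", "b"), c("AAAAAAAAAA", "AAACCCAAAA"))
  D <- compute_distances(aln)
  expect_equal(D["a", "b"], 0.3)

  ident <- msa(c("x", "y", "z"), rep("MKVL", 3))
  expect_true(all(compute_distances(ident) == 0))

  withr::with_seed(31, {
    rows <- vapply(1:5, function(i) {
      s <- rand_protein(40)
      gaps <- sample(40, 5)
      ch <- strsplit(s, "")[[1]]; ch[gaps] <- "-"
      paste(ch, collapse = "")
    }, character(1))
    aln2 <- msa(paste0("t", 1:5), rows)
    D2 <- compute_distances(aln2)
    m <- as.matrix(aln2)
    for (i in 1:4) for (j in (i + 1):5) {
      ok <- m[i, ] != "-" & m[j, ] != "-"
      expect_equal(D2[i, j], sum(m[i, ok] != m[j, ok]) / sum(ok))
    }
  })

  # zero comparable columns -> error naming the pair
  bad <- msa(c("p", "q"), c("A---", "--CC"))
  expect_error(compute_distances(bad), "'p' and 'q'")

  # gamma correction is the standard transform
  Dg <- compute_distances(aln, model = "gamma", alpha = 2)
  expect_equal(Dg["a", "b"], 2 * ((1 - 0.3)^(-1 / 2) - 1))
})

test_that("neighbor joining solves the three-point case and two taxa", {
  d <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighbor_joining(d)
  bl <- stats::setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(unname(bl[c("A", "B", "C")]), c(1, 1, 3))

  d2 <- matrix(c(0, 5, 5, 0), 2, 2, dimnames = list(c("A", "B"),
                                                    c("A", "B")))
  tr2 <- neighbor_joining(d2)
  expect_equal(sum(tr2$edge.length), 5)

  expect_error(neighbor_joining(matrix(c(0, 1, 2, 0), 2, 2)),
               "not symmetric")
})

test_that("NJ recovers the topology of additive matrices (ape oracle)", {
  withr::with_seed(32, {
    for (trial in 1:25) {
      n <- sample(4:12, 1)
      tr <- ape::rtree(n, br = function(k) stats::runif(k, 0.1, 1))
      D <- stats::cophenetic(tr)
      ord <- sort(rownames(D))
      mine <- neighbor_joining(D[ord, ord])
      expect_equal(ape::dist.topo(ape::unroot(mine), ape::unroot(tr)), 0,
                   ignore_attr = TRUE)
      # and the recovered split structure matches ape's own NJ
      anj <- ape::nj(D[ord, ord])
      expect_equal(ape::dist.topo(ape::unroot(mine), ape::unroot(anj)), 0,
                   ignore_attr = TRUE)
    }
  })
})

test_that("Fitch scores match forced cases and phangorn on all topologies", {
  ident <- msa(paste0("t", 1:4), rep("MKVL", 4))
  tr <- ape::read.tree(text = "((t1,t2),(t3,t4));")
  expect_equal(fitch_parsimony_score(tr, ident), 0)

  col <- msa(paste0("t", 1:4), c("A", "A", "C", "C"))
  expect_equal(fitch_parsimony_score(tr, col), 1)

  expect_error(fitch_parsimony_score(
    ape::read.tree(text = "((t1,t9),(t3,t4));"), col), "t9")

  withr::with_seed(33, {
    seqs <- stats::setNames(vapply(1:6, function(i) rand_protein(20),
                                   character(1)), paste0("t", 1:6))
    aln <- msa(names(seqs), unname(seqs))
    pd <- phangorn::phyDat(stats::setNames(strsplit(unname(seqs), ""),
                                           names(seqs)), type = "AA")
    alltr <- phangorn::allTrees(6, tip.label = names(seqs))
    mine <- vapply(alltr, function(tt) fitch_parsimony_score(tt, aln),
                   numeric(1))
    ref <- vapply(alltr, function(tt) phangorn::parsimony(tt, pd),
                  numeric(1))
    expect_equal(mine, ref, ignore_attr = TRUE)
  })
})

test_that("Fitch score is invariant under re-rooting and label symmetry", {
  withr::with_seed(34, {
    seqs <- stats::setNames(vapply(1:7, function(i) rand_protein(15),
                                   character(1)), paste0("t", 1:7))
    aln <- msa(names(seqs), unname(seqs))
    tr <- ape::rtree(7, tip.label = names(seqs))
    s0 <- fitch_parsimony_score(tr, aln)
    for (og in sample(names(seqs), 3)) {
      expect_equal(fitch_parsimony_score(ape::root(tr, og), aln), s0)
    }
  })
})

test_that("NNI search never worsens and reaches the optimum with signal", {
  withr::with_seed(35, {
    for (trial in 1:5) {
      sim <- evolve_on_tree(n = 6, len = 60, rate = 0.15)
      aln <- msa(names(sim$seqs), unname(sim$seqs))
      start <- neighbor_joining(compute_distances(aln))
      s0 <- fitch_parsimony_score(start, aln)
      best <- parsimony_search(aln, start)
      expect_lte(attr(best, "pscore"), s0)
      alltr <- phangorn::allTrees(6, tip.label = names(sim$seqs))
      opt <- min(vapply(alltr, function(tt) fitch_parsimony_score(tt, aln),
                        numeric(1)))
      expect_equal(attr(best, "pscore"), opt)
    }
    # identical sequences: any topology, score 0
    ident <- msa(paste0("t", 1:5), rep("MMMM", 5))
    expect_equal(attr(parsimony_search(ident), "pscore"), 0)
  })
})

test_that("bootstrap supports behave like resampling statistics", {
  # every column supports the same split -> support 100 at any reps
  aln <- msa(paste0("t", 1:4),
             c("AAAAAAAA", "AAAAAAAA", "CCCCCCCC", "CCCCCCCC"))
  st <- bootstrap_supports(aln, "nj", reps = 25, seed = 1)
  expect_equal(nrow(st$supports), 1)
  expect_equal(st$supports$support, 100L)

  # fixed seed -> identical supports across runs; supports within [0,100]
  withr::with_seed(36, {
    rows <- vapply(1:5, function(i) rand_protein(30), character(1))
  })
  aln2 <- msa(paste0("t", 1:5), rows)
  a <- bootstrap_supports(aln2, "mp", reps = 60, seed = 99)
  b <- bootstrap_supports(aln2, "mp", reps = 60, seed = 99)
  expect_identical(a$supports, b$supports)
  expect_true(all(a$supports$support >= 0 & a$supports$support <= 100))

  expect_error(bootstrap_supports(aln2, "zz"), "arg")
})

test_that("rooting and clade queries walk the tree correctly", {
  aln <- msa(c("X", "ref1", "ref2", "ref3", "out"),
             c("AAAAAAAAAA", "AAAAAAAAAC", "GGGGGGGGGG", "GGGGGGGGGC",
               "MMMMMMMMMM"))
  st <- bootstrap_supports(aln, "nj", reps = 50, seed = 3)
  rt <- root_at_outgroup(st, "out")
  expect_true(rt$rooted)
  scc <- smallest_containing_clade(rt, "X")
  expect_equal(scc$sister, "ref1")
  expect_true(scc$support >= 0 && scc$support <= 100)

  expect_error(root_at_outgroup(st, "nothere"), "not a leaf")
  expect_error(smallest_containing_clade(rt, "ghost"), "not in tree")

  # rooting preserves the unrooted bipartition set
  pre <- sort(bhlhscan:::tree_bipartitions(st$tree))
  post <- sort(bhlhscan:::tree_bipartitions(ape::unroot(rt$tree)))
  expect_equal(pre, post)
})

test_that("supported trees round-trip through Newick with node labels", {
  withr::with_seed(37, {
    rows <- vapply(1:6, function(i) rand_protein(25), character(1))
  })
  aln <- msa(paste0("t", 1:6), rows)
  st <- bootstrap_supports(aln, "nj", reps = 40, seed = 5)
  tmp <- withr::local_tempfile(fileext = ".nwk")
  write_supported_tree(st, tmp)
  back <- read_supported_tree(tmp)
  ord <- order(st$supports$bipartition)
  ord2 <- order(back$supports$bipartition)
  expect_equal(back$supports$bipartition[ord2],
               st$supports$bipartition[ord])
  expect_equal(back$supports$support[ord2], st$supports$support[ord])
})
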