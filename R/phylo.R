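# Internally implemented tree inference: p-distances, neighbor joining,
# Fitch parsimony with NNI hill climbing, column-bootstrap supports,
# outgroup rooting and monophyly queries.
#
# Trees are `ape::phylo` objects. Bootstrapped trees are wrapped in class
# "supported_tree": list(tree, supports, method, reps, seed, rooted) where
# supports is a tibble keyed by a canonical bipartition string.

# ---- adjacency-list tree utilities ------------------------------------------

# undirected adjacency list (plain list indexed by node id; tips are
# 1..n_tip) from a phylo object
adj_from_phylo <- function(phy) {
  phy <- ape::unroot(phy)
  nmax <- max(phy$edge)
  adj <- vector("list", nmax)
  for (k in seq_len(nrow(phy$edge))) {
    a <- phy$edge[k, 1]; b <- phy$edge[k, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  attr(adj, "n_tip") <- length(phy$tip.label)
  attr(adj, "tip_label") <- phy$tip.label
  adj
}

# rebuild a phylo object (no edge lengths unless `lens` given as a function
# id-pair -> length) by rooting the adjacency at the internal neighbor of
# tip 1
phylo_from_adj <- function(adj, lens = NULL) {
  n <- attr(adj, "n_tip")
  labels <- attr(adj, "tip_label")
  if (n == 2) {
    phy <- list(edge = rbind(c(3L, 1L), c(3L, 2L)), tip.label = labels,
                Nnode = 1L)
    if (!is.null(lens)) phy$edge.length <- c(lens(1L, 2L) / 2,
                                             lens(1L, 2L) / 2)
    class(phy) <- "phylo"
    return(phy)
  }
  root_id <- adj[[1L]][1L]
  # DFS assigning new numbers: tips keep 1..n, internals n+1, n+2, ...
  newid <- integer(length(adj))
  newid[seq_len(n)] <- seq_len(n)
  nxt <- n + 1L
  parent <- integer(0); child <- integer(0); elen <- numeric(0)
  stack_node <- root_id; stack_from <- 0L
  while (length(stack_node)) {
    v <- stack_node[1L]; from <- stack_from[1L]
    stack_node <- stack_node[-1L]; stack_from <- stack_from[-1L]
    if (v > n) { newid[v] <- nxt; nxt <- nxt + 1L }
    if (from > 0L) {
      parent <- c(parent, newid[from]); child <- c(child, v)
      if (!is.null(lens)) elen <- c(elen, lens(from, v))
    }
    kids <- setdiff(adj[[v]], from)
    if (length(kids)) {
      stack_node <- c(kids, stack_node)
      stack_from <- c(rep(v, length(kids)), stack_from)
    }
  }
  child <- ifelse(child > n, newid[child], child)
  phy <- list(edge = cbind(parent, child, deparse.level = 0),
              tip.label = labels, Nnode = nxt - n - 1L)
  if (!is.null(lens)) phy$edge.length <- elen
  class(phy) <- "phylo"
  phy$edge <- matrix(as.integer(phy$edge), ncol = 2)
  phy
}

# the two NNI rearrangements across each internal edge
nni_neighbors <- function(adj) {
  n <- attr(adj, "n_tip")
  out <- list()
  nodes <- which(!vapply(adj, is.null, logical(1)))
  internals <- nodes[nodes > n]
  for (u in internals) {
    for (v in adj[[u]]) {
      if (v <= n || v < u) next
      a <- setdiff(adj[[u]], v)
      c2 <- setdiff(adj[[v]], u)
      b <- a[2]
      for (cc in c2) {
        new <- adj
        new[[u]] <- c(setdiff(new[[u]], b), cc)
        new[[v]] <- c(setdiff(new[[v]], cc), b)
        new[[b]] <- c(setdiff(new[[b]], u), v)
        new[[cc]] <- c(setdiff(new[[cc]], v), u)
        out[[length(out) + 1L]] <- new
      }
    }
  }
  out
}

# ---- distances --------------------------------------------------------------

#' Pairwise distances from an alignment
#'
#' Proportion of mismatching residues over pairwise-deleted (gap-free in both
#' rows) columns, optionally gamma-corrected as
#' `d = alpha * ((1 - p)^(-1/alpha) - 1)`.
#'
#' @param aln A `bhlh_msa` alignment with >= 2 rows.
#' @param model `"p"` (default) or `"gamma"`.
#' @param alpha Gamma shape parameter used when `model = "gamma"`.
#' @param weights Optional non-negative per-column weights (bootstrap
#'   resampling uses integer weights).
#' @return A symmetric distance matrix with zero diagonal.
#' @export
compute_distances <- function(aln, model = c("p", "gamma"), alpha = 1,
                              weights = NULL) {
  model <- match.arg(model)
  if (nrow(aln) < 2) stop("need at least two rows", call. = FALSE)
  m <- as.matrix(aln)
  L <- ncol(m)
  w <- weights %||% rep(1, L)
  stopifnot(length(w) == L)
  gap <- m == "-" | m == "X" | m == "*"
  n <- nrow(m)
  D <- matrix(0, n, n, dimnames = list(aln$id, aln$id))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- !gap[i, ] & !gap[j, ]
      denom <- sum(w[ok])
      if (denom == 0) {
        stop("no comparable columns between '", aln$id[i], "' and '",
             aln$id[j], "'", call. = FALSE)
      }
      p <- sum(w[ok & m[i, ] != m[j, ]]) / denom
      d <- if (model == "p") p else {
        if (p >= 1) p <- 1 - 1e-9
        alpha * ((1 - p)^(-1 / alpha) - 1)
      }
      D[i, j] <- D[j, i] <- d
    }
  }
  D
}

# ---- neighbor joining -------------------------------------------------------

#' Neighbor-joining tree
#'
#' Standard Saitou-Nei agglomeration with deterministic tie-breaking (the
#' smallest index pair on equal Q values). Negative branch lengths are
#' clamped to zero, the deficit being absorbed by the sister edge.
#'
#' @param d A symmetric distance matrix with dimnames (or a `dist`).
#' @return An unrooted `phylo` tree with branch lengths.
#' @export
neighbor_joining <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-8))) {
    stop("distance matrix is not symmetric", call. = FALSE)
  }
  n <- nrow(d)
  if (n < 2) stop("need at least two taxa", call. = FALSE)
  labels <- rownames(d) %||% paste0("t", seq_len(n))
  ids <- seq_len(n)            # node ids of active cluster roots
  nxt <- n + 1L
  adj <- vector("list", 2 * n)
  lens <- new.env(parent = emptyenv())
  set_len <- function(a, b, v) assign(paste(sort(c(a, b)), collapse = "-"),
                                      max(v, 0), envir = lens)
  get_len <- function(a, b) get(paste(sort(c(a, b)), collapse = "-"),
                                envir = lens)
  link <- function(a, b, v) {
    adj[[a]] <<- c(adj[[a]], b)
    adj[[b]] <<- c(adj[[b]], a)
    set_len(a, b, v)
  }
  D <- d
  while (length(ids) > 3) {
    r <- length(ids)
    R <- rowSums(D)
    Q <- (r - 2) * D - outer(R, R, "+")
    diag(Q) <- Inf
    # smallest (i, j), i < j, among minima
    best <- which(Q <= min(Q) + 1e-12, arr.ind = TRUE)
    best <- best[best[, 1] < best[, 2], , drop = FALSE]
    best <- best[order(best[, 1], best[, 2]), , drop = FALSE]
    i <- best[1, 1]; j <- best[1, 2]
    li <- D[i, j] / 2 + (R[i] - R[j]) / (2 * (r - 2))
    lj <- D[i, j] - li
    if (li < 0) { lj <- D[i, j]; li <- 0 }
    if (lj < 0) { li <- D[i, j]; lj <- 0 }
    u <- nxt; nxt <- nxt + 1L
    link(ids[i], u, li)
    link(ids[j], u, lj)
    du <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(r), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], du[keep]),
               c(du[keep], 0))
    ids <- c(ids[keep], u)
    rownames(D) <- colnames(D) <- NULL
  }
  if (length(ids) == 3) {
    u <- nxt
    va <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
    vb <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
    vc <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
    link(ids[1], u, va); link(ids[2], u, vb); link(ids[3], u, vc)
  } else {
    if (ids[1] <= n && ids[2] <= n) {
      # two-taxon tree: a single edge
      attr(adj, "n_tip") <- n
      attr(adj, "tip_label") <- labels
      return(phylo_from_adj(adj, lens = function(a, b) D[1, 2]))
    }
    link(ids[1], ids[2], D[1, 2])
  }
  attr(adj, "n_tip") <- n
  attr(adj, "tip_label") <- labels
  phylo_from_adj(adj, lens = get_len)
}

# ---- Fitch parsimony --------------------------------------------------------

# per-column leaf state bitmasks; gaps and ambiguity codes are wildcards
fitch_masks <- function(aln) {
  m <- as.matrix(aln)
  L <- ncol(m)
  masks <- matrix(0L, nrow = nrow(m), ncol = L)
  for (cc in seq_len(L)) {
    col <- m[, cc]
    amb <- col %in% c("-", "X", "*", "?")
    states <- sort(unique(col[!amb]))
    if (length(states) == 0) {
      masks[, cc] <- 1L
      next
    }
    full <- bitwShiftL(1L, length(states)) - 1L
    masks[, cc] <- ifelse(amb, full,
                          bitwShiftL(1L, match(col, states) - 1L))
  }
  rownames(masks) <- aln$id
  masks
}

fitch_score_adj <- function(adj, masks, weights = NULL) {
  n <- attr(adj, "n_tip")
  labels <- attr(adj, "tip_label")
  L <- ncol(masks)
  w <- weights %||% rep(1, L)
  row_of <- match(labels, rownames(masks))
  cost <- 0
  combine <- function(m1, m2) {
    a <- bitwAnd(m1, m2)
    zero <- a == 0L
    cost <<- cost + sum(w[zero])
    a[zero] <- bitwOr(m1[zero], m2[zero])
    a
  }
  node_mask <- function(v, from) {
    if (v <= n) return(masks[row_of[v], ])
    kids <- setdiff(adj[[v]], from)
    mk <- node_mask(kids[1], v)
    for (k in kids[-1]) mk <- combine(mk, node_mask(k, v))
    mk
  }
  start <- adj[[1L]][1L]
  mk <- node_mask(start, 1L)
  combine(mk, masks[row_of[1L], ])
  cost
}

#' Fitch small-parsimony score of a tree
#'
#' Sum over alignment columns of the minimum number of state changes; gaps
#' and ambiguous residues contribute wildcard state sets.
#'
#' @param tree A `phylo` tree (rooted or unrooted) whose tips all appear in
#'   `aln`.
#' @param aln A `bhlh_msa` alignment.
#' @param weights Optional per-column weights.
#' @return The integer parsimony score.
#' @export
fitch_parsimony_score <- function(tree, aln, weights = NULL) {
  if (!all(tree$tip.label %in% aln$id)) {
    stop("tree tip(s) missing from alignment: ",
         paste(setdiff(tree$tip.label, aln$id), collapse = ", "),
         call. = FALSE)
  }
  ord <- match(tree$tip.label, aln$id)
  aln <- new_msa(aln$id[ord], aln$aligned[ord])
  fitch_score_adj(adj_from_phylo(tree), fitch_masks(aln), weights)
}

#' Parsimony tree search by NNI hill climbing
#'
#' Starting from a given tree (by default the neighbor-joining tree on
#' p-distances), repeatedly applies the best score-improving
#' nearest-neighbor-interchange until a local optimum or `max_rounds`.
#'
#' @param aln A `bhlh_msa` alignment.
#' @param start Optional starting `phylo`; defaults to the NJ tree.
#' @param weights Optional per-column weights.
#' @param max_rounds Maximum number of NNI improvement rounds.
#' @return An unrooted `phylo` (no branch lengths); attribute `"pscore"`
#'   carries the final parsimony score.
#' @export
parsimony_search <- function(aln, start = NULL, weights = NULL,
                             max_rounds = 50) {
  if (is.null(start)) {
    start <- neighbor_joining(compute_distances(aln, weights = weights))
  }
  ord <- match(start$tip.label, aln$id)
  aln2 <- new_msa(aln$id[ord], aln$aligned[ord])
  masks <- fitch_masks(aln2)
  adj <- adj_from_phylo(start)
  score <- fitch_score_adj(adj, masks, weights)
  n <- attr(adj, "n_tip")
  if (n >= 4) {
    for (round in seq_len(max_rounds)) {
      nbs <- nni_neighbors(adj)
      if (!length(nbs)) break
      sc <- vapply(nbs, fitch_score_adj, numeric(1),
                   masks = masks, weights = weights)
      if (min(sc) >= score) break
      k <- which.min(sc)
      adj <- nbs[[k]]
      score <- sc[k]
    }
  }
  out <- phylo_from_adj(adj)
  attr(out, "pscore") <- score
  out
}

# ---- bipartitions and supports ----------------------------------------------

# canonical key: the side not containing the alphabetically first taxon,
# sorted and joined by "|"
bipartition_key <- function(leafset, all_leaves) {
  ref <- min(all_leaves)
  side <- if (ref %in% leafset) setdiff(all_leaves, leafset) else leafset
  paste(sort(side), collapse = "|")
}

# tip label sets below each node (list indexed by ape node number)
node_tipsets <- function(phy) {
  n <- length(phy$tip.label)
  phy2 <- ape::reorder.phylo(phy, "postorder")
  sets <- vector("list", n + phy$Nnode)
  for (i in seq_len(n)) sets[[i]] <- phy$tip.label[i]
  for (k in seq_len(nrow(phy2$edge))) {
    p <- phy2$edge[k, 1]; ch <- phy2$edge[k, 2]
    sets[[p]] <- c(sets[[p]], sets[[ch]])
  }
  sets
}

# canonical keys of the non-trivial bipartitions of a tree
tree_bipartitions <- function(phy) {
  n <- length(phy$tip.label)
  sets <- node_tipsets(phy)
  keys <- character(0)
  for (v in seq_along(sets)) {
    if (v <= n) next
    sz <- length(sets[[v]])
    if (sz >= 2 && sz <= n - 2) {
      keys <- c(keys, bipartition_key(sets[[v]], phy$tip.label))
    }
  }
  unique(keys)
}

#' Bootstrap supports for a tree
#'
#' Builds a reference tree on the full alignment, then resamples columns with
#' replacement `reps` times, rebuilding a tree with the same method each
#' time. The support of each internal bipartition of the reference tree is
#' the percentage of replicate trees containing it, rounded to the nearest
#' integer (.5 rounds up).
#'
#' @param aln A `bhlh_msa` alignment.
#' @param method `"nj"` (neighbor joining on p-distances) or `"mp"` (Fitch
#'   parsimony with NNI search).
#' @param reps Number of bootstrap replicates (>= 1).
#' @param seed Integer seed driving the column resampling.
#' @param model,alpha Distance model passed to [compute_distances()] for
#'   `method = "nj"`.
#' @return A `supported_tree`: list with `tree` (`phylo`), `supports`
#'   (tibble of `bipartition`, `leaves`, `support`), `method`, `reps`,
#'   `seed`, `rooted`.
#' @export
bootstrap_supports <- function(aln, method = c("nj", "mp"), reps = 1000,
                               seed = 1000, model = "p", alpha = 1) {
  method <- match.arg(method)
  if (reps < 1) stop("reps must be >= 1", call. = FALSE)
  build <- function(weights) {
    if (method == "nj") {
      neighbor_joining(compute_distances(aln, model = model, alpha = alpha,
                                         weights = weights))
    } else {
      parsimony_search(aln, weights = weights)
    }
  }
  ref <- build(NULL)
  keys <- tree_bipartitions(ref)
  counts <- stats::setNames(rep(0L, length(keys)), keys)
  L <- msa_ncol(aln)
  with_seed(seed, {
    for (r in seq_len(reps)) {
      w <- tabulate(sample.int(L, L, replace = TRUE), nbins = L)
      bt <- build(w)
      hit <- intersect(keys, tree_bipartitions(bt))
      counts[hit] <- counts[hit] + 1L
    }
  })
  supports <- tibble(
    bipartition = keys,
    leaves = lapply(keys, function(k) strsplit(k, "|", fixed = TRUE)[[1]]),
    support = as.integer(round_half_up(100 * counts / reps))
  )
  structure(list(tree = ref, supports = supports, method = method,
                 reps = reps, seed = seed, rooted = FALSE),
            class = "supported_tree")
}

#' @export
print.supported_tree <- function(x, ...) {
  cat("Supported tree (", x$method, ", ", x$reps, " bootstrap replicates, ",
      if (x$rooted) "rooted" else "unrooted", ")\n", sep = "")
  cat("  ", length(x$tree$tip.label), " tips, ",
      nrow(x$supports), " internal bipartitions\n", sep = "")
  invisible(x)
}

#' Tidy a supported tree into its bipartition table
#' @param x A `supported_tree`.
#' @param ... Unused.
#' @return A tibble with one row per internal bipartition.
#' @export
tidy.supported_tree <- function(x, ...) x$supports

#' Root a supported tree at an outgroup
#'
#' Places the root on the outgroup's pendant edge. Bipartition supports are
#' keyed by leaf sets, so they carry over to the corresponding clades.
#'
#' @param st A `supported_tree`.
#' @param outgroup A tip label present in the tree.
#' @return A rooted `supported_tree`.
#' @export
root_at_outgroup <- function(st, outgroup) {
  if (!outgroup %in% st$tree$tip.label) {
    stop("outgroup '", outgroup, "' is not a leaf of the tree",
         call. = FALSE)
  }
  st$tree <- ape::root(st$tree, outgroup = outgroup, resolve.root = TRUE)
  st$rooted <- TRUE
  st
}

#' Smallest clade containing a taxon
#'
#' On a rooted supported tree, returns the leaf set of the taxon's smallest
#' enclosing non-trivial clade (minus the taxon itself) together with that
#' clade's bootstrap support.
#'
#' @param st A rooted `supported_tree`.
#' @param taxon A tip label.
#' @return A list with `sister` (character vector of leaves) and `support`
#'   (integer, `NA` if the clade has no internal-edge support).
#' @export
smallest_containing_clade <- function(st, taxon) {
  phy <- st$tree
  if (!st$rooted) stop("tree must be rooted first", call. = FALSE)
  tipno <- match(taxon, phy$tip.label)
  if (is.na(tipno)) stop("taxon '", taxon, "' not in tree", call. = FALSE)
  parent <- phy$edge[phy$edge[, 2] == tipno, 1]
  sets <- node_tipsets(phy)
  clade <- sets[[parent]]
  key <- bipartition_key(clade, phy$tip.label)
  sup <- st$supports$support[match(key, st$supports$bipartition)]
  list(sister = setdiff(clade, taxon), support = sup)
}

# ---- newick I/O -------------------------------------------------------------

#' Write / read a supported tree as Newick
#'
#' Supports are encoded as internal node labels.
#'
#' @param st A `supported_tree`.
#' @param path File path.
#' @export
write_supported_tree <- function(st, path) {
  phy <- st$tree
  n <- length(phy$tip.label)
  sets <- node_tipsets(phy)
  lab <- character(phy$Nnode)
  for (v in (n + 1):(n + phy$Nnode)) {
    key <- bipartition_key(sets[[v]], phy$tip.label)
    hit <- match(key, st$supports$bipartition)
    lab[v - n] <- if (is.na(hit)) "" else as.character(st$supports$support[hit])
  }
  phy$node.label <- lab
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' @rdname write_supported_tree
#' @param rooted Logical; whether the stored tree should be treated as
#'   rooted.
#' @export
read_supported_tree <- function(path, rooted = FALSE) {
  phy <- ape::read.tree(path)
  n <- length(phy$tip.label)
  sets <- node_tipsets(phy)
  keys <- character(0); sup <- integer(0)
  for (v in (n + 1):(n + phy$Nnode)) {
    lb <- phy$node.label[v - n]
    if (!is.null(lb) && !is.na(lb) && nzchar(lb)) {
      keys <- c(keys, bipartition_key(sets[[v]], phy$tip.label))
      sup <- c(sup, as.integer(lb))
    }
  }
  structure(list(tree = phy,
                 supports = tibble(
                   bipartition = keys,
                   leaves = lapply(keys, function(k)
                     strsplit(k, "|", fixed = TRUE)[[1]]),
                   support = sup),
                 method = NA_character_, reps = NA_integer_,
                 seed = NA_integer_, rooted = rooted),
            class = "supported_tree")
}
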