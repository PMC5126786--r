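# Global pairwise and progressive multiple alignment of protein sequences.
#
# Alignments are represented as a tibble with columns `id` and `aligned`
# (equal-length gapped strings), class "bhlh_msa". Degapping any row
# reproduces the input sequence.

new_msa <- function(id, aligned) {
  stopifnot(length(unique(nchar(aligned))) <= 1)
  structure(tibble(id = id, aligned = aligned), class = c("bhlh_msa", class(tibble())))
}

#' Number of columns of an alignment
#' @param aln A `bhlh_msa` alignment.
#' @return Integer column count.
#' @export
msa_ncol <- function(aln) if (nrow(aln) == 0) 0L else nchar(aln$aligned[[1]])

#' Alignment as a character matrix
#' @param x A `bhlh_msa` alignment.
#' @param ... Unused.
#' @return A rows-by-columns character matrix with row names from `id`.
#' @export
as.matrix.bhlh_msa <- function(x, ...) {
  m <- do.call(rbind, strsplit(x$aligned, "", fixed = TRUE))
  if (is.null(m)) m <- matrix(character(), 0, 0)
  rownames(m) <- x$id
  m
}

# column frequency profile (20 x ncol); gap mass simply missing so heavily
# gapped columns score low
profile_freq <- function(rows) {
  n <- length(rows)
  L <- nchar(rows[[1]])
  m <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  f <- matrix(0, nrow = 20, ncol = L, dimnames = list(AA_ALPHABET, NULL))
  for (a in seq_along(AA_ALPHABET)) {
    f[a, ] <- colSums(m == AA_ALPHABET[a]) / n
  }
  f
}

# Needleman-Wunsch with affine gaps on a precomputed column-score matrix
# smat (nA x nB). Returns list(path_a, path_b): integer vectors with 0 for a
# gap. Tie order on traceback: diagonal > up (consume A) > left (consume B).
nw_core <- function(smat, open, ext) {
  n <- nrow(smat)
  m <- ncol(smat)
  if (n == 0 && m == 0) return(list(a = integer(), b = integer(), score = 0))
  if (n == 0) {
    return(list(a = rep(0L, m), b = seq_len(m),
                score = -(open + (m - 1) * ext)))
  }
  if (m == 0) {
    return(list(a = seq_len(n), b = rep(0L, n),
                score = -(open + (n - 1) * ext)))
  }
  NEG <- -1e12
  M <- matrix(NEG, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1) # gap in B, consume A ("up")
  Y <- matrix(NEG, n + 1, m + 1) # gap in A, consume B ("left")
  M[1, 1] <- 0
  if (n >= 1) X[2:(n + 1), 1] <- -(open + (0:(n - 1)) * ext)
  if (m >= 1) Y[1, 2:(m + 1)] <- -(open + (0:(m - 1)) * ext)
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      M[i, j] <- smat[i - 1, j - 1] +
        max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1])
      X[i, j] <- max(M[i - 1, j] - open, X[i - 1, j] - ext, Y[i - 1, j] - open)
      Y[i, j] <- max(M[i, j - 1] - open, X[i, j - 1] - open, Y[i, j - 1] - ext)
    }
  }
  score <- max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
  # traceback; state preference M > X > Y throughout
  pick <- function(i, j) {
    v <- c(M[i, j], X[i, j], Y[i, j])
    which.max(v + c(2e-9, 1e-9, 0))
  }
  i <- n + 1; j <- m + 1
  st <- pick(i, j)
  pa <- integer(0); pb <- integer(0)
  while (i > 1 || j > 1) {
    if (st == 1) { # M: consumed a[i-1], b[j-1]
      pa <- c(i - 1L, pa); pb <- c(j - 1L, pb)
      i <- i - 1; j <- j - 1
      st <- pick(i, j)
    } else if (st == 2) { # X: consumed a[i-1]
      pa <- c(i - 1L, pa); pb <- c(0L, pb)
      prev <- c(M[i - 1, j] - open, X[i - 1, j] - ext, Y[i - 1, j] - open)
      i <- i - 1
      st <- which.max(prev + c(2e-9, 1e-9, 0))
    } else { # Y: consumed b[j-1]
      pa <- c(0L, pa); pb <- c(j - 1L, pb)
      prev <- c(M[i, j - 1] - open, X[i, j - 1] - open, Y[i, j - 1] - ext)
      j <- j - 1
      st <- which.max(prev + c(2e-9, 1e-9, 0))
    }
  }
  list(a = pa, b = pb, score = score)
}

#' Optimal global pairwise alignment with affine gaps
#'
#' Needleman-Wunsch alignment under a [scoring_scheme()]. A gap of length k
#' costs `gap_open + (k - 1) * gap_ext`. Traceback is deterministic with tie
#' order diagonal > up > left.
#'
#' @param a,b Protein sequences (plain strings; one may be empty).
#' @param scoring A [scoring_scheme()].
#' @return A list with `alignment` (a two-row `bhlh_msa`) and `score`.
#' @export
pairwise_global_align <- function(a, b, scoring = scoring_scheme()) {
  ia <- if (nchar(a)) aa_encode(a) else integer(0)
  ib <- if (nchar(b)) aa_encode(b) else integer(0)
  smat <- scoring$matrix[ia, ib, drop = FALSE]
  res <- nw_core(smat, scoring$gap_open, scoring$gap_ext)
  ach <- strsplit(a, "", fixed = TRUE)[[1]]
  bch <- strsplit(b, "", fixed = TRUE)[[1]]
  ga <- ifelse(res$a == 0, "-", ach[pmax(res$a, 1)])
  gb <- ifelse(res$b == 0, "-", bch[pmax(res$b, 1)])
  list(alignment = new_msa(c("a", "b"), c(paste(ga, collapse = ""),
                                          paste(gb, collapse = ""))),
       score = res$score)
}

# align two profiles (lists of gapped rows); returns merged rows in order
# c(rows_a, rows_b)
profile_profile_align <- function(rows_a, rows_b, scoring) {
  fa <- profile_freq(rows_a)
  fb <- profile_freq(rows_b)
  smat <- t(fa) %*% scoring$matrix %*% fb
  res <- nw_core(smat, scoring$gap_open, scoring$gap_ext)
  expand <- function(rows, path) {
    m <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
    out <- matrix("-", nrow = length(rows), ncol = length(path))
    keep <- path != 0
    out[, keep] <- m[, path[keep], drop = FALSE]
    apply(out, 1, paste, collapse = "")
  }
  c(expand(rows_a, res$a), expand(rows_b, res$b))
}

#' Progressive multiple sequence alignment
#'
#' Guide-tree progressive alignment: pairwise global alignment scores are
#' turned into distances, a neighbor-joining guide tree orders the
#' profile-profile merges, and rows are returned in input order.
#'
#' @param seqs Named character vector of protein sequences (>= 1).
#' @param scoring A [scoring_scheme()].
#' @return A `bhlh_msa` alignment.
#' @export
progressive_align <- function(seqs, scoring = scoring_scheme()) {
  if (is.null(names(seqs)) || anyDuplicated(names(seqs))) {
    stop("seqs must be uniquely named", call. = FALSE)
  }
  n <- length(seqs)
  if (n == 1) return(new_msa(names(seqs), unname(seqs)))
  ids <- names(seqs)
  # pairwise score matrix -> normalized distances
  S <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    ii <- aa_encode(seqs[[i]])
    S[i, i] <- sum(scoring$matrix[cbind(ii, ii)])
  }
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      S[i, j] <- S[j, i] <- pairwise_global_align(seqs[[i]], seqs[[j]],
                                                  scoring)$score
    }
  }
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ref <- min(S[i, i], S[j, j])
      d <- if (ref > 0) 1 - S[i, j] / ref else 1
      D[i, j] <- D[j, i] <- max(d, 0)
    }
  }
  if (n == 2) {
    merged <- profile_profile_align(seqs[1], seqs[2], scoring)
    return(new_msa(ids, unname(merged)))
  }
  guide <- neighbor_joining(D)
  # recursive merge following the guide tree
  edge <- guide$edge
  merge_node <- function(node) {
    if (node <= n) return(stats::setNames(unname(seqs[guide$tip.label[node]]),
                                          guide$tip.label[node]))
    kids <- edge[edge[, 1] == node, 2]
    prof <- merge_node(kids[1])
    for (k in kids[-1]) {
      other <- merge_node(k)
      merged <- profile_profile_align(prof, other, scoring)
      prof <- stats::setNames(merged, c(names(prof), names(other)))
    }
    prof
  }
  root <- setdiff(unique(edge[, 1]), edge[, 2])
  prof <- merge_node(root)
  new_msa(ids, unname(prof[ids]))
}

#' Insert a sequence into a fixed reference alignment
#'
#' Aligns one sequence against the profile of an existing alignment. The
#' reference columns are preserved in order; new all-gap columns are inserted
#' only where the sequence has residues the profile cannot absorb.
#'
#' @param aln A non-empty `bhlh_msa` reference alignment.
#' @param seq Protein sequence to add.
#' @param id Row id for the new sequence.
#' @param scoring A [scoring_scheme()].
#' @return A `bhlh_msa` with `nrow(aln) + 1` rows; the added row degaps to
#'   `seq`.
#' @export
align_to_profile <- function(aln, seq, id = "query",
                             scoring = scoring_scheme()) {
  if (nrow(aln) == 0) stop("reference alignment is empty", call. = FALSE)
  merged <- profile_profile_align(aln$aligned, seq, scoring)
  new_msa(c(aln$id, id), unname(merged))
}

#' Read and write alignments
#'
#' Aligned FASTA is handled through Biostrings; the Clustal writer emits the
#' conventional interleaved block format.
#'
#' @param path File path.
#' @return `read_alignment()` returns a `bhlh_msa`.
#' @export
read_alignment <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  new_msa(names(x), as.character(x))
}

#' @rdname read_alignment
#' @param aln A `bhlh_msa` alignment.
#' @param format `"fasta"` or `"clustal"`.
#' @export
write_alignment <- function(aln, path, format = c("fasta", "clustal")) {
  format <- match.arg(format)
  if (format == "fasta") {
    x <- Biostrings::AAStringSet(stats::setNames(aln$aligned, aln$id))
    Biostrings::writeXStringSet(x, path)
  } else {
    w <- max(nchar(aln$id)) + 3
    lines <- c("CLUSTAL W multiple sequence alignment", "")
    L <- msa_ncol(aln)
    for (s in seq(1, max(L, 1), by = 60)) {
      e <- min(s + 59, L)
      block <- sprintf("%-*s%s", w, aln$id, substr(aln$aligned, s, e))
      lines <- c(lines, block, "")
    }
    writeLines(lines, path)
  }
  invisible(path)
}

#' Flag low-scoring alignment rows
#'
#' Automated stand-in for by-eye inspection of an alignment: reports each
#' row's mean identity to the other rows and flags rows below a cutoff.
#'
#' @param aln A `bhlh_msa` alignment.
#' @param min_identity Rows with mean pairwise identity below this fraction
#'   are flagged.
#' @return A tibble with `id`, `mean_identity`, `flagged`.
#' @export
alignment_report <- function(aln, min_identity = 0.3) {
  m <- as.matrix(aln)
  n <- nrow(m)
  ident <- vapply(seq_len(n), function(i) {
    others <- setdiff(seq_len(n), i)
    if (!length(others)) return(1)
    mean(vapply(others, function(j) {
      ok <- m[i, ] != "-" & m[j, ] != "-"
      if (!any(ok)) return(0)
      mean(m[i, ok] == m[j, ok])
    }, numeric(1)))
  }, numeric(1))
  tibble(id = aln$id, mean_identity = ident,
         flagged = ident < min_identity)
}
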