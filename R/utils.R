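# shared constants and small helpers

# the 20 standard amino acids, in BLOSUM row order used throughout
AA_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

DNA_ALPHABET <- c("A", "C", "G", "T", "N")

#' Default protein scoring scheme
#'
#' Bundles a symmetric substitution matrix with affine gap penalties. A gap of
#' length k costs `gap_open + (k - 1) * gap_ext`. The default matrix is
#' BLOSUM62 restricted to the 20 standard residues, with gap open 10 and gap
#' extend 1 -- the conventional protein-alignment defaults.
#'
#' @param matrix A 20x20 (or larger) symmetric integer substitution matrix
#'   with residue dimnames, or the string `"BLOSUM62"`.
#' @param gap_open,gap_ext Non-negative gap penalties.
#' @return An object of class `scoring_scheme`.
#' @export
scoring_scheme <- function(matrix = "BLOSUM62", gap_open = 10, gap_ext = 1) {
  if (is.character(matrix) && identical(matrix, "BLOSUM62")) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    matrix <- e$BLOSUM62[AA_ALPHABET, AA_ALPHABET]
  }
  stopifnot(is.matrix(matrix), isTRUE(all.equal(matrix, t(matrix))))
  if (gap_open < 0 || gap_ext < 0) {
    stop("gap penalties must be non-negative", call. = FALSE)
  }
  structure(list(matrix = matrix, gap_open = gap_open, gap_ext = gap_ext),
            class = "scoring_scheme")
}

# integer-encode a protein string over AA_ALPHABET; unknown residues error
# unless allow_x, in which case X/*/- map to 0
aa_encode <- function(seq, allow_x = FALSE) {
  ch <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  idx <- match(ch, AA_ALPHABET)
  if (anyNA(idx)) {
    bad <- ch[is.na(idx)]
    if (allow_x && all(bad %in% c("X", "*", "-", "U", "B", "Z", "J", "O"))) {
      idx[is.na(idx)] <- 0L
    } else {
      stop("invalid residue letter(s): ",
           paste(unique(bad), collapse = ", "), call. = FALSE)
    }
  }
  idx
}

aa_decode <- function(idx) paste(AA_ALPHABET[idx], collapse = "")

# round to nearest integer, .5 away from zero (supports are printed integers)
round_half_up <- function(x) floor(x + 0.5)

degap <- function(x) gsub("-", "", x, fixed = TRUE)

`%||%` <- function(a, b) if (is.null(a)) b else a

# evaluate expr with a private RNG state seeded from `seed`, restoring the
# caller's stream afterwards
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else rm(".Random.seed", envir = globalenv())
  })
  expr
}
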