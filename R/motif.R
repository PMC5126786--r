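# Detection of bHLH-like domains in protein sequences: profile scan,
# validation against a configurable conserved-site table, and segmentation
# of the ~60-column motif frame into basic / helix1 / loop / helix2.

#' Conserved-site table
#'
#' A set of motif-frame columns with the residue letters accepted at each,
#' plus the minimum number of matching sites a candidate domain must reach.
#' The packaged default ([default_site_table()]) lists 19 sites; the table is
#' an editable configuration, not a fixed constant.
#'
#' @param sites A data frame with columns `column` (1-based motif-frame
#'   index, strictly increasing) and `allowed` (string of accepted residue
#'   letters); an optional `weight` column is preserved.
#' @param min_matches Minimum number of matched sites for a domain to pass.
#' @return A tibble of class `conserved_site_table`.
#' @export
conserved_site_table <- function(sites, min_matches = 9) {
  sites <- as_tibble(sites)
  stopifnot(all(c("column", "allowed") %in% names(sites)))
  if (any(diff(sites$column) <= 0)) {
    stop("site columns must be strictly increasing", call. = FALSE)
  }
  letters_ok <- vapply(strsplit(sites$allowed, "", fixed = TRUE),
                       function(x) length(x) > 0 && all(x %in% AA_ALPHABET),
                       logical(1))
  if (!all(letters_ok)) {
    stop("allowed residues must be non-empty subsets of the 20-letter alphabet",
         call. = FALSE)
  }
  if (!"weight" %in% names(sites)) sites$weight <- 1
  attr(sites, "min_matches") <- min_matches
  class(sites) <- c("conserved_site_table", class(sites))
  sites
}

#' @rdname conserved_site_table
#' @param path TSV file with columns `column`, `allowed`, optional `weight`.
#' @export
read_site_table <- function(path, min_matches = 9) {
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  conserved_site_table(df, min_matches = min_matches)
}

#' @rdname conserved_site_table
#' @export
default_site_table <- function(min_matches = 9) {
  read_site_table(system.file("extdata", "conserved_sites.tsv",
                              package = "bhlhscan"),
                  min_matches = min_matches)
}

#' Motif region scheme
#'
#' Half-open is not used here: boundaries are 1-based closed column
#' intervals that must tile `1..frame_length` in order
#' basic, helix1, loop, helix2.
#'
#' @param frame_length Number of columns in the motif frame.
#' @param basic,helix1,loop,helix2 Length-2 integer vectors `c(first, last)`.
#' @return A list of class `region_scheme`.
#' @export
region_scheme <- function(frame_length = 60, basic = c(1, 15),
                          helix1 = c(16, 30), loop = c(31, 44),
                          helix2 = c(45, 60)) {
  b <- list(basic = basic, helix1 = helix1, loop = loop, helix2 = helix2)
  flat <- unlist(b)
  if (b$basic[1] != 1 || b$helix2[2] != frame_length ||
      any(diff(flat) < 0) ||
      b$helix1[1] != b$basic[2] + 1 || b$loop[1] != b$helix1[2] + 1 ||
      b$helix2[1] != b$loop[2] + 1) {
    stop("region boundaries must be ordered, disjoint and cover the frame",
         call. = FALSE)
  }
  structure(list(frame_length = frame_length, boundaries = b),
            class = "region_scheme")
}

#' @rdname region_scheme
#' @param path YAML file with keys `frame_length`, `basic`, `helix1`,
#'   `loop`, `helix2`.
#' @export
read_region_scheme <- function(path) {
  y <- yaml::read_yaml(path)
  region_scheme(frame_length = y$frame_length,
                basic = unlist(y$basic), helix1 = unlist(y$helix1),
                loop = unlist(y$loop), helix2 = unlist(y$helix2))
}

# region label of a motif-frame column
region_of_column <- function(column, scheme) {
  b <- scheme$boundaries
  dplyr::case_when(
    column >= b$basic[1] & column <= b$basic[2] ~ "basic",
    column >= b$helix1[1] & column <= b$helix1[2] ~ "helix1",
    column >= b$loop[1] & column <= b$loop[2] ~ "loop",
    column >= b$helix2[1] & column <= b$helix2[2] ~ "helix2",
    TRUE ~ NA_character_
  )
}

#' Build a motif profile from reference domain sequences
#'
#' @param motifs Character vector of reference motif sequences, all aligned
#'   to the same frame (equal length; gaps allowed).
#' @return A list of class `motif_profile` with the position frequency
#'   matrix, the majority-rule consensus and the frame length.
#' @export
build_motif_profile <- function(motifs) {
  stopifnot(length(motifs) >= 1)
  if (length(unique(nchar(motifs))) != 1) {
    stop("reference motifs must share one frame length", call. = FALSE)
  }
  pfm <- profile_freq(motifs)
  consensus <- paste(AA_ALPHABET[apply(pfm, 2, which.max)], collapse = "")
  structure(list(pfm = pfm, consensus = consensus,
                 frame_length = nchar(consensus)),
            class = "motif_profile")
}

#' Check a motif-frame row against a conserved-site table
#'
#' @param aligned_row A motif-frame string (gaps allowed) whose length equals
#'   the table's frame (here, the length implied by its largest column).
#' @param table A [conserved_site_table()].
#' @param frame_length Expected row length.
#' @return A list with `matches`, `pass` and `matched_sites` (the matching
#'   columns). A gap at a site never matches.
#' @export
check_conserved_sites <- function(aligned_row, table, frame_length = 60) {
  if (nchar(aligned_row) != frame_length) {
    stop("aligned row length ", nchar(aligned_row),
         " does not match frame length ", frame_length, call. = FALSE)
  }
  ch <- strsplit(aligned_row, "", fixed = TRUE)[[1]]
  hit <- vapply(seq_len(nrow(table)), function(k) {
    r <- ch[table$column[k]]
    r != "-" && grepl(r, table$allowed[k], fixed = TRUE)
  }, logical(1))
  list(matches = sum(hit),
       pass = sum(hit) >= attr(table, "min_matches"),
       matched_sites = table$column[hit])
}

#' Scan a protein for bHLH-like domains
#'
#' Local profile alignment of the protein against the reference motif
#' profile, followed by conserved-site validation. Hits are extracted
#' non-overlapping in descending score order and returned sorted by start.
#' Hits failing the conserved-site threshold are retained with `pass =
#' FALSE` so that filter decisions stay auditable; accepted domains are the
#' rows with `pass == TRUE`.
#'
#' @param seq Protein sequence (string over the 20-letter alphabet).
#' @param protein_id Identifier recorded in the output.
#' @param profile A [build_motif_profile()] result.
#' @param scheme A [region_scheme()].
#' @param site_table A [conserved_site_table()].
#' @param scoring A [scoring_scheme()].
#' @param min_score Minimum profile alignment score of a hit.
#' @param min_coverage Minimum fraction of profile columns a hit must align;
#'   guards against high-scoring fragments much shorter than the domain.
#' @param max_hits Cap on reported hits per protein.
#' @return A tibble with one row per hit: `protein_id`, `start`, `end`
#'   (0-based half-open residue coordinates), `score`, `aligned_row`,
#'   `site_matches`, `pass`, and list columns `matched_sites`, `insertions`
#'   (tibbles of `column`, `residue`) and `col_res` (0-based protein residue
#'   per frame column, `NA` at gaps).
#' @export
scan_protein <- function(seq, profile, scheme = region_scheme(),
                         site_table = default_site_table(),
                         protein_id = "protein",
                         scoring = scoring_scheme(),
                         min_score = 60, min_coverage = 0.5, max_hits = 10) {
  empty <- tibble(protein_id = character(), start = integer(),
                  end = integer(), score = numeric(),
                  aligned_row = character(), site_matches = integer(),
                  pass = logical(), matched_sites = list(),
                  insertions = list(), col_res = list())
  if (nchar(seq) == 0) return(empty)
  subject <- aa_encode(seq)
  L <- profile$frame_length
  pssm <- t(profile$pfm) %*% scoring$matrix   # L x 20
  raw <- sw_scan_cpp(pssm, subject, scoring$gap_open, scoring$gap_ext,
                     min_score, as.integer(max_hits))
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  rows <- purrr::map(raw, function(h) {
    qp <- h$q_path; sp <- h$s_path
    covered <- sum(qp > 0 & sp > 0)
    if (covered < min_coverage * L) return(NULL)
    row <- rep("-", L)
    col_res <- rep(NA_integer_, L)
    both <- qp > 0 & sp > 0
    row[qp[both]] <- ch[sp[both]]
    col_res[qp[both]] <- sp[both] - 1L
    ins_cols <- integer(0); ins_res <- character(0)
    last_col <- NA_integer_
    for (k in seq_along(qp)) {
      if (qp[k] > 0) last_col <- qp[k]
      if (qp[k] == 0 && sp[k] > 0) {
        anchor <- if (is.na(last_col)) {
          nx <- qp[qp > 0]
          if (length(nx)) nx[1] else 1L
        } else last_col
        ins_cols <- c(ins_cols, anchor)
        ins_res <- c(ins_res, ch[sp[k]])
      }
    }
    check <- check_conserved_sites(paste(row, collapse = ""), site_table,
                                   frame_length = L)
    tibble(protein_id = protein_id,
           start = h$s_start - 1L, end = as.integer(h$s_end),
           score = h$score,
           aligned_row = paste(row, collapse = ""),
           site_matches = as.integer(check$matches),
           pass = check$pass,
           matched_sites = list(check$matched_sites),
           insertions = list(tibble(column = ins_cols, residue = ins_res)),
           col_res = list(col_res))
  })
  rows <- purrr::compact(rows)
  if (!length(rows)) return(empty)
  dplyr::arrange(dplyr::bind_rows(rows), .data$start)
}

#' Segment a motif hit into its structural regions
#'
#' Maps each region of the scheme onto the hit: a region whose frame columns
#' are all gaps is `missing`, a region with some gaps is `partial`, and a
#' fully aligned region is `complete`. Insertions are assigned to the region
#' containing their anchor column.
#'
#' @param hit One row of a [scan_protein()] result.
#' @param scheme A [region_scheme()].
#' @return A tibble with `region`, `col_start`, `col_end`, `status`,
#'   `res_start`, `res_end` (0-based half-open protein coordinates, `NA`
#'   when missing) and `n_insertions`.
#' @export
segment_regions <- function(hit, scheme = region_scheme()) {
  stopifnot(nrow(hit) == 1)
  col_res <- hit$col_res[[1]]
  ins <- hit$insertions[[1]]
  ins_region <- if (nrow(ins)) region_of_column(ins$column, scheme) else character(0)
  purrr::map_dfr(names(scheme$boundaries), function(rg) {
    b <- scheme$boundaries[[rg]]
    cols <- col_res[b[1]:b[2]]
    aligned <- !is.na(cols)
    status <- if (!any(aligned)) "missing"
              else if (!all(aligned)) "partial" else "complete"
    tibble(region = rg, col_start = b[1], col_end = b[2], status = status,
           res_start = if (any(aligned)) min(cols[aligned]) else NA_integer_,
           res_end = if (any(aligned)) max(cols[aligned]) + 1L else NA_integer_,
           n_insertions = sum(ins_region == rg))
  })
}

#' Derive a conserved-site table from reference motifs
#'
#' Picks the `n_sites` most conserved profile columns (highest majority
#' residue frequency; ties to the left) and accepts, at each, every residue
#' observed there among the references. Useful when the survey targets a
#' reference compendium rather than the curated default table.
#'
#' @param motifs Character vector of equal-length reference motifs.
#' @param n_sites Number of sites to select.
#' @param min_matches Threshold stored on the resulting table.
#' @return A [conserved_site_table()].
#' @export
site_table_from_motifs <- function(motifs, n_sites = 19, min_matches = 9) {
  pfm <- profile_freq(motifs)
  conserv <- apply(pfm, 2, max)
  cols <- sort(order(-conserv, seq_along(conserv))[seq_len(min(n_sites,
                                                               ncol(pfm)))])
  allowed <- vapply(cols, function(j) {
    paste(AA_ALPHABET[pfm[, j] > 0], collapse = "")
  }, character(1))
  conserved_site_table(tibble(column = cols, allowed = allowed),
                       min_matches = min_matches)
}
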