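# The packaged brown-planthopper bHLH gene catalog, the insect
# family-by-species count matrix, the family-to-group map, and the counting
# operations that reproduce the published summary numbers.

SUPPORT_COLS <- c("nj", "mp", "ml", "bayes")
GROUPS <- c("A", "B", "C", "D", "E", "F")

#' Read a bHLH gene catalog
#'
#' The catalog TSV has columns `gene_name`, `family`, `homolog`, `nj`,
#' `mp`, `ml`, `bayes`, `gene_id`, `evidence`. Support entries are integers
#' in 0..100 or the literal `n/m` ("no monophyletic group"), which is
#' parsed to `NA` -- a distinct marker, never coerced to zero -- and written
#' back as `n/m`.
#'
#' @param path TSV file path.
#' @return A tibble of class `bhlh_catalog`.
#' @export
read_catalog <- function(path) {
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                        col_types = readr::cols(.default = "c"))
  required <- c("gene_name", "family", "homolog", SUPPORT_COLS, "evidence")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("catalog is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(df$gene_name)) {
    stop("duplicate gene_name(s): ",
         paste(unique(df$gene_name[duplicated(df$gene_name)]),
               collapse = ", "), call. = FALSE)
  }
  for (cc in SUPPORT_COLS) {
    v <- df[[cc]]
    num <- suppressWarnings(as.integer(v))
    bad <- !is.na(v) & is.na(num) & v != "n/m"
    if (any(bad)) {
      stop("invalid support value(s) in column '", cc, "': ",
           paste(unique(v[bad]), collapse = ", "), call. = FALSE)
    }
    if (any(num < 0 | num > 100, na.rm = TRUE)) {
      stop("support values must lie in [0, 100]", call. = FALSE)
    }
    df[[cc]] <- num
  }
  if (!"gene_id" %in% names(df)) df$gene_id <- NA_character_
  out <- as_tibble(df[, c("gene_name", "family", "homolog", SUPPORT_COLS,
                          "gene_id", "evidence")])
  class(out) <- c("bhlh_catalog", class(out))
  out
}

#' @rdname read_catalog
#' @param catalog A catalog tibble.
#' @export
write_catalog <- function(catalog, path) {
  df <- as.data.frame(catalog)
  for (cc in SUPPORT_COLS) {
    df[[cc]] <- ifelse(is.na(df[[cc]]), "n/m", as.character(df[[cc]]))
  }
  readr::write_tsv(df, path)
  invisible(path)
}

#' The packaged N. lugens bHLH catalog (60 genes)
#'
#' Transcribed verbatim from the published gene list: per-gene family,
#' fruit-fly (or pea-aphid) homolog, per-method supports and transcription
#' evidence.
#'
#' @return A `bhlh_catalog` tibble with 60 rows.
#' @export
nlbhlh_catalog <- function() {
  read_catalog(system.file("extdata", "nlbhlh_catalog.tsv",
                           package = "bhlhscan"))
}

#' Read a family-by-species count matrix
#'
#' First column `family`, second `group`, then one integer column per
#' species code.
#'
#' @param path TSV file path.
#' @return A tibble of class `family_matrix`.
#' @export
read_family_matrix <- function(path) {
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  stopifnot(names(df)[1] == "family", names(df)[2] == "group")
  if (!all(df$group %in% GROUPS)) {
    stop("groups must be one of ", paste(GROUPS, collapse = ", "),
         call. = FALSE)
  }
  counts <- df[, -(1:2)]
  if (any(unlist(counts) < 0)) stop("counts must be >= 0", call. = FALSE)
  out <- as_tibble(df)
  class(out) <- c("family_matrix", class(out))
  out
}

#' The packaged twelve-insect family count matrix
#' @return A `family_matrix` tibble (45 families x 13 species columns).
#' @export
insect_family_matrix <- function() {
  read_family_matrix(system.file("extdata", "insect_family_matrix.tsv",
                                 package = "bhlhscan"))
}

matrix_species_col <- function(matrix, species) {
  if (!species %in% names(matrix)[-(1:2)]) {
    stop("unknown species column '", species, "'", call. = FALSE)
  }
  matrix[[species]]
}

#' Family-to-group map
#'
#' Built from a family matrix's `group` column, optionally extended with
#' additional entries. The packaged default adds `Met -> C`: the published
#' count matrix folds the Met family into its group C total while the gene
#' catalog lists Met as its own family, and group counting needs the
#' explicit entry.
#'
#' @param matrix A `family_matrix` (default the packaged one).
#' @param extra Named character vector of additional `family = group`
#'   entries.
#' @return A named character vector family -> group letter.
#' @export
family_group_map <- function(matrix = insect_family_matrix(),
                             extra = c(Met = "C")) {
  m <- stats::setNames(matrix$group, matrix$family)
  if (length(extra)) m[names(extra)] <- extra
  if (!all(m %in% GROUPS)) stop("groups restricted to A-F", call. = FALSE)
  m
}

#' Map a family to its high-order group
#' @param family Family name(s).
#' @param groups A [family_group_map()].
#' @return Group letter(s).
#' @export
family_to_group <- function(family, groups = family_group_map()) {
  unknown <- setdiff(family, names(groups))
  if (length(unknown)) {
    stop("family not in group map: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  unname(groups[family])
}

#' Count catalog members per high-order group
#'
#' @param catalog A `bhlh_catalog`.
#' @param groups A [family_group_map()] covering every catalog family.
#' @return A tibble `group`, `n` over all six groups (zeros included);
#'   counts sum to the catalog size.
#' @export
count_by_group <- function(catalog, groups = family_group_map()) {
  g <- family_to_group(catalog$family, groups)
  tab <- table(factor(g, levels = GROUPS))
  tibble(group = GROUPS, n = as.integer(tab))
}

#' Tally transcription evidence labels
#' @param catalog A `bhlh_catalog`.
#' @return A tibble `evidence`, `n`; tallies partition the catalog.
#' @export
evidence_tally <- function(catalog) {
  if (nrow(catalog) == 0) return(tibble(evidence = character(),
                                        n = integer()))
  tab <- table(catalog$evidence)
  tibble(evidence = names(tab), n = as.integer(tab))
}

#' Families present for a species
#' @param matrix A `family_matrix`.
#' @param species Species column name.
#' @return Number of families with count > 0.
#' @export
families_present <- function(matrix, species) {
  sum(matrix_species_col(matrix, species) > 0)
}

#' Families with more than one member for a species
#' @inheritParams families_present
#' @return Number of families with count > 1.
#' @export
multi_member_family_count <- function(matrix, species) {
  sum(matrix_species_col(matrix, species) > 1)
}

#' Total gene count of a species column
#' @inheritParams families_present
#' @return Column sum.
#' @export
column_total <- function(matrix, species) {
  sum(matrix_species_col(matrix, species))
}
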