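# Mapping gene models onto motif coordinates, intron classification by
# motif region, and intron summary statistics.

# introns of a model in transcription order: genomic 0-based half-open
# intervals plus the CDS offset (nt upstream of the intron)
model_introns <- function(model) {
  ex <- model$exons[[1]]
  k <- nrow(ex)
  if (k < 2) {
    return(tibble(index = integer(), start = integer(), end = integer(),
                  length = integer(), cds_offset = integer()))
  }
  lens <- ex$end - ex$start
  offs <- cumsum(lens)[-k]
  purrr::map_dfr(seq_len(k - 1), function(i) {
    if (model$strand == "+") {
      s <- ex$end[i]; e <- ex$start[i + 1]
    } else {
      s <- ex$end[i + 1]; e <- ex$start[i]
    }
    tibble(index = i, start = as.integer(s), end = as.integer(e),
           length = as.integer(e - s), cds_offset = as.integer(offs[i]))
  })
}

#' Genomic footprint of a protein interval
#'
#' Maps a protein residue interval (for instance a detected motif) onto
#' codon-resolved genomic intervals, split at introns and strand-aware.
#'
#' @param model One-row gene-model tibble.
#' @param motif Length-2 integer vector: 0-based half-open protein residue
#'   interval.
#' @return A tibble of genomic intervals (`start`, `end`, 0-based
#'   half-open) in transcription order; their widths sum to `3 *
#'   (motif[2] - motif[1])`.
#' @export
motif_genomic_footprint <- function(model, motif) {
  ex <- model$exons[[1]]
  cds_len <- sum(ex$end - ex$start)
  nt0 <- 3 * motif[1]; nt1 <- 3 * motif[2]
  if (nt0 < 0 || nt1 > cds_len || nt1 <= nt0) {
    stop("motif interval outside the coding region", call. = FALSE)
  }
  out <- list()
  c0 <- 0
  for (i in seq_len(nrow(ex))) {
    w <- ex$end[i] - ex$start[i]
    lo <- max(nt0, c0); hi <- min(nt1, c0 + w)
    if (lo < hi) {
      if (model$strand == "+") {
        gs <- ex$start[i] + (lo - c0); ge <- ex$start[i] + (hi - c0)
      } else {
        gs <- ex$end[i] - (hi - c0); ge <- ex$end[i] - (lo - c0)
      }
      out[[length(out) + 1]] <- tibble(start = as.integer(gs),
                                       end = as.integer(ge))
    }
    c0 <- c0 + w
  }
  dplyr::bind_rows(out)
}

#' Classify introns by the motif region they interrupt
#'
#' Each intron of the model receives its length, phase (0/1/2 bases into a
#' codon) and location: the motif region (`basic`, `helix1`, `loop`,
#' `helix2`) containing the interrupted codon, or `outside_motif`. An intron
#' interrupting a codon belongs to the region of that codon; an intron
#' falling exactly between two codons belongs to the region of the following
#' codon.
#'
#' @param model One-row gene-model tibble.
#' @param motif Length-2 protein residue interval of the motif (0-based
#'   half-open), or `NULL` when the gene carries no motif.
#' @param scheme A [region_scheme()].
#' @return A tibble: `gene_id`, `index`, `length`, `phase`, `location`.
#' @export
classify_introns <- function(model, motif = NULL,
                             scheme = region_scheme()) {
  introns <- model_introns(model)
  if (nrow(introns) == 0) {
    return(tibble(gene_id = character(), index = integer(),
                  length = integer(), phase = integer(),
                  location = character()))
  }
  phase <- introns$cds_offset %% 3L
  codon <- introns$cds_offset %/% 3L  # interrupted codon, or following one
  location <- rep("outside_motif", nrow(introns))
  if (!is.null(motif)) {
    inside <- codon >= motif[1] & codon < motif[2]
    column <- codon[inside] - motif[1] + 1L
    location[inside] <- region_of_column(column, scheme)
  }
  tibble(gene_id = model$gene_id, index = introns$index,
         length = introns$length, phase = as.integer(phase),
         location = location)
}

#' Summarize intron structure across genes
#'
#' @param records A tibble of intron records ([classify_introns()] output,
#'   possibly bound over genes).
#' @param n_genes Total number of genes surveyed (intronless genes carry no
#'   records).
#' @param per_gene_denominator `"intron_bearing"` (default) divides the
#'   total intron count by the number of genes with at least one intron;
#'   `"all"` divides by `n_genes`.
#' @return A one-row tibble: gene and intron counts, min/max/mean intron
#'   length (mean rounded to the nearest bp), mean introns per gene, and
#'   per-region counts of motif-interrupting introns.
#' @export
summarize_introns <- function(records, n_genes,
                              per_gene_denominator = c("intron_bearing",
                                                       "all")) {
  per_gene_denominator <- match.arg(per_gene_denominator)
  n_bearing <- length(unique(records$gene_id))
  total <- nrow(records)
  denom <- if (per_gene_denominator == "all") n_genes else n_bearing
  regions <- c("basic", "helix1", "loop", "helix2")
  reg_counts <- vapply(regions, function(r) sum(records$location == r),
                       integer(1))
  motif_genes <- length(unique(
    records$gene_id[records$location %in% regions]))
  tibble(
    n_genes = n_genes,
    n_intronless = n_genes - n_bearing,
    n_intron_bearing = n_bearing,
    total_introns = total,
    mean_per_gene = if (denom > 0) total / denom else 0,
    min_length = if (total) min(records$length) else NA_integer_,
    max_length = if (total) max(records$length) else NA_integer_,
    mean_length = if (total) as.integer(round_half_up(mean(records$length)))
                  else NA_integer_,
    in_basic = reg_counts[["basic"]],
    in_helix1 = reg_counts[["helix1"]],
    in_loop = reg_counts[["loop"]],
    in_helix2 = reg_counts[["helix2"]],
    motif_introns = sum(reg_counts),
    motif_interrupted_genes = motif_genes
  )
}
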