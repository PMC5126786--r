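# End-to-end orchestration: genome survey, candidate classification, and
# report generation (catalog- and family-matrix-style outputs).

#' Survey configuration
#'
#' @param flank Hit extension in bp.
#' @param min_search_score Minimum translated-search alignment score.
#' @param min_motif_score Minimum profile alignment score of a domain hit.
#' @param min_matches Conserved-site threshold (of the table's sites).
#' @param min_reciprocal_overlap Redundancy threshold.
#' @param min_coverage Minimum fraction of the motif frame a hit must
#'   cover.
#' @return A list of class `survey_config`.
#' @export
survey_config <- function(flank = 10000, min_search_score = 40,
                          min_motif_score = 60, min_matches = 9,
                          min_reciprocal_overlap = 0.8,
                          min_coverage = 0.5) {
  structure(as.list(environment()), class = "survey_config")
}

#' Run the genome survey
#'
#' Searches every scaffold with each reference domain sequence (translated
#' local alignment), extends and merges hits into loci, intersects loci
#' with the supplied gene models, and runs the candidate filter cascade.
#'
#' @param scaffolds Scaffold tibble (`id`, `seq`) or named character
#'   vector, or a FASTA path.
#' @param reference_seqs Named character vector of reference domain
#'   sequences used as queries (and as the motif profile).
#' @param gene_models Gene-model tibble or a GFF3 path.
#' @param config A [survey_config()].
#' @param scheme,site_table,scoring Motif-validation settings.
#' @param out_dir Optional directory: accepted proteins (FASTA), gene
#'   models (GFF3), audit trail (TSV) and a provenance YAML are written
#'   there.
#' @return A list of class `bhlh_survey`: `accepted`, `audit`, `loci`,
#'   `hits`, `counts`, `config`.
#' @export
run_survey <- function(scaffolds, reference_seqs, gene_models,
                       config = survey_config(),
                       scheme = region_scheme(),
                       site_table = default_site_table(config$min_matches),
                       scoring = scoring_scheme(), out_dir = NULL) {
  if (is.character(scaffolds) && length(scaffolds) == 1 &&
      file.exists(scaffolds)) {
    scaffolds <- read_scaffolds(scaffolds)
  }
  sc <- as_scaffold_tbl(scaffolds)
  if (is.character(gene_models)) gene_models <- read_gene_models(gene_models)
  frames <- translate_scaffold_frames(sc)
  hits <- purrr::map_dfr(names(reference_seqs), function(q) {
    translated_local_search(reference_seqs[[q]], sc, scoring = scoring,
                            min_score = config$min_search_score,
                            query_id = q, frames = frames)
  })
  lens <- stats::setNames(nchar(sc$seq), sc$id)
  loci <- extend_and_merge(hits, flank = config$flank,
                           scaffold_lengths = lens)
  cands <- candidates_from_loci(loci, gene_models, sc)
  profile <- build_motif_profile(unname(reference_seqs))
  if (is.null(cands) || nrow(cands) == 0) {
    res <- list(accepted = tibble(), audit = tibble(gene_id = character(),
                                                    stage = character(),
                                                    pass = logical(),
                                                    reason = character()))
  } else {
    res <- candidate_filter_cascade(
      cands, profile, scheme = scheme, site_table = site_table,
      scoring = scoring, min_motif_score = config$min_motif_score,
      min_reciprocal_overlap = config$min_reciprocal_overlap)
  }
  counts <- tibble(
    stage = c("scaffolds", "search_hits", "loci", "candidate_genes",
              "accepted"),
    n = c(nrow(sc), nrow(hits), nrow(loci),
          if (is.null(cands)) 0L else nrow(cands), nrow(res$accepted)))
  out <- structure(list(accepted = res$accepted, audit = res$audit,
                        loci = loci, hits = hits, counts = counts,
                        config = config),
                   class = "bhlh_survey")
  if (!is.null(out_dir)) write_survey(out, out_dir)
  out
}

write_survey <- function(survey, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  acc <- survey$accepted
  if (nrow(acc)) {
    Biostrings::writeXStringSet(
      Biostrings::AAStringSet(stats::setNames(acc$protein, acc$gene_id)),
      file.path(out_dir, "accepted_proteins.fasta"))
    write_gene_models(acc, file.path(out_dir, "accepted_models.gff3"))
  }
  readr::write_tsv(survey$audit, file.path(out_dir, "filter_audit.tsv"))
  yaml::write_yaml(c(survey$config,
                     list(counts = stats::setNames(as.list(survey$counts$n),
                                                   survey$counts$stage))),
                   file.path(out_dir, "survey_provenance.yml"))
  invisible(out_dir)
}

#' @export
print.bhlh_survey <- function(x, ...) {
  cat("bHLH genome survey\n")
  for (i in seq_len(nrow(x$counts))) {
    cat(sprintf("  %-16s %d\n", x$counts$stage[i], x$counts$n[i]))
  }
  invisible(x)
}

#' Glance at a survey result
#' @param x A `bhlh_survey`.
#' @param ... Unused.
#' @return One-row tibble of per-stage counts.
#' @export
glance.bhlh_survey <- function(x, ...) {
  tidyr::pivot_wider(x$counts, names_from = "stage", values_from = "n")
}

#' Extract the detected domain sequence of each accepted candidate
#' @param survey A `bhlh_survey`.
#' @return A tibble `id`, `seq` of motif-region sequences.
#' @export
survey_motifs <- function(survey) {
  acc <- survey$accepted
  purrr::map_dfr(seq_len(nrow(acc)), function(i) {
    h <- acc$motif_hit[[i]]
    tibble(id = acc$gene_id[i],
           seq = substr(acc$protein[i], h$start + 1, h$end))
  })
}

#' Run the classification stage
#'
#' Classifies candidate domain sequences against ordered reference sets,
#' names them, and emits a catalog-schema table.
#'
#' @param candidates Tibble `id`, `seq` of candidate domain sequences
#'   (for instance [survey_motifs()] output).
#' @param refsets List of [reference_set()] objects in cascade order.
#' @param threshold,majority,methods,reps,seed Cascade and bootstrap
#'   settings (see [classify_candidates()]).
#' @param prefix Species prefix for gene names.
#' @param out_dir Optional directory for the assignment TSV and catalog
#'   TSV.
#' @return A list of class `bhlh_classification`: `assignments`, `catalog`.
#' @export
run_classification <- function(candidates, refsets, threshold = 50,
                               majority = 0.5, methods = c("nj", "mp"),
                               reps = 200, seed = 1000, prefix = "Nl",
                               out_dir = NULL) {
  if (nrow(candidates) == 0) {
    return(structure(list(assignments = tibble(), catalog = tibble()),
                     class = "bhlh_classification"))
  }
  asg <- classify_candidates(candidates, refsets, threshold = threshold,
                             majority = majority, methods = methods,
                             reps = reps, seed = seed)
  nm <- name_paralogs(asg, prefix = prefix)
  asg$name <- nm$name[match(asg$id, nm$id)]
  sup <- function(m) {
    vapply(asg$methods, function(d) {
      i <- match(m, d$method)
      if (is.na(i)) NA_integer_ else d$support[i]
    }, integer(1))
  }
  catalog <- tibble(
    gene_name = asg$name,
    family = asg$family,
    homolog = asg$ortholog,
    nj = sup("nj"), mp = sup("mp"), ml = sup("ml"), bayes = sup("bayes"),
    gene_id = asg$id,
    evidence = NA_character_,
    status = asg$status)
  out <- structure(list(assignments = asg, catalog = catalog),
                   class = "bhlh_classification")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_tsv(catalog, file.path(out_dir, "catalog.tsv"))
    flat <- asg[, c("id", "name", "family", "status", "refset",
                    "best_support")]
    readr::write_tsv(flat, file.path(out_dir, "assignments.tsv"))
  }
  out
}

#' Build a family-by-species matrix from catalogs
#'
#' @param catalogs Named list (names = species codes) of catalog tibbles
#'   (anything with a `family` column).
#' @param groups A [family_group_map()] covering every family seen.
#' @return A `family_matrix` tibble with one row per family and one count
#'   column per species.
#' @export
emit_family_matrix <- function(catalogs, groups = family_group_map()) {
  fams <- unique(unlist(lapply(catalogs, function(x)
    x$family[!is.na(x$family)])))
  unknown <- setdiff(fams, names(groups))
  if (length(unknown)) {
    stop("family not in group map: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  out <- tibble(family = fams, group = unname(groups[fams]))
  for (sp in names(catalogs)) {
    f <- catalogs[[sp]]$family
    out[[sp]] <- vapply(fams, function(x) sum(f == x, na.rm = TRUE),
                        integer(1))
  }
  out <- dplyr::arrange(out, .data$group, .data$family)
  class(out) <- c("family_matrix", class(out))
  out
}

#' Compare one species column of two family matrices
#'
#' Reports per-family count differences; families absent from one matrix
#' count as zero there.
#'
#' @param a,b `family_matrix` tibbles.
#' @param species Species column present in both.
#' @return A tibble `family`, `count_a`, `count_b`, `match`.
#' @export
compare_family_matrix <- function(a, b, species) {
  fams <- union(a$family, b$family)
  ca <- stats::setNames(matrix_species_col(a, species), a$family)
  cb <- stats::setNames(matrix_species_col(b, species), b$family)
  va <- ifelse(fams %in% names(ca), ca[fams], 0L)
  vb <- ifelse(fams %in% names(cb), cb[fams], 0L)
  tibble(family = fams, count_a = as.integer(va),
         count_b = as.integer(vb), match = va == vb)
}
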