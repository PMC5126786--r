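# Per-candidate ingroup phylogenetic tests and the monophyly/support
# decision cascade that assigns candidates to ortholog families.

#' Reference set for ingroup analyses
#'
#' A labelled collection of reference domain sequences grouped by family and
#' high-order group, plus the outgroup sequence used to root every ingroup
#' tree.
#'
#' @param members Tibble with columns `id`, `species`, `family`, `group`,
#'   `seq`.
#' @param outgroup_id,outgroup_seq The outgroup leaf (id must not collide
#'   with a member id).
#' @param label Short label (for instance `"primary"`).
#' @return A list of class `reference_set`.
#' @export
reference_set <- function(members, outgroup_id, outgroup_seq,
                          label = "reference") {
  members <- as_tibble(members)
  stopifnot(all(c("id", "family", "group", "seq") %in% names(members)),
            nrow(members) >= 1)
  if (outgroup_id %in% members$id) {
    stop("outgroup id collides with a member id", call. = FALSE)
  }
  structure(list(members = members, outgroup_id = outgroup_id,
                 outgroup_seq = outgroup_seq, label = label),
            class = "reference_set")
}

#' Ingroup phylogenetic test of one candidate
#'
#' Aligns the candidate with all reference members of the tested family's
#' high-order group plus the outgroup, builds a bootstrapped tree per
#' method, roots it at the outgroup and inspects the candidate's smallest
#' enclosing clade. An ortholog is reported only when the candidate's sister
#' set is exactly one reference leaf.
#'
#' @param candidate_id,candidate_seq The candidate leaf.
#' @param refset A [reference_set()].
#' @param family Family whose group defines the ingroup; the reference set
#'   must hold at least two members of that group (or of the whole set when
#'   `scope = "all"`).
#' @param scope `"group"` restricts the ingroup to the family's high-order
#'   group; `"all"` uses every reference member (useful for small reference
#'   sets whose groups hold a single family).
#' @param methods Tree methods, subset of `c("nj", "mp")`.
#' @param reps Bootstrap replicates per method.
#' @param seed Integer seed (each method uses an offset-derived stream).
#' @param scoring A [scoring_scheme()] for the alignment.
#' @param model Distance model for the NJ method.
#' @return A tibble of per-method results: `method`, `ortholog` (`NA` when
#'   no single-leaf sister), `support`, `family`, plus list column `sister`.
#' @export
ingroup_test <- function(candidate_id, candidate_seq, refset, family,
                         methods = c("nj", "mp"), reps = 1000, seed = 1000,
                         scoring = scoring_scheme(), model = "p",
                         scope = c("group", "all")) {
  scope <- match.arg(scope)
  fams <- refset$members$family
  if (!family %in% fams) {
    stop("family '", family, "' not present in reference set '",
         refset$label, "'", call. = FALSE)
  }
  grp <- refset$members$group[match(family, fams)]
  ing <- if (scope == "group") {
    refset$members[refset$members$group == grp, ]
  } else {
    refset$members
  }
  if (nrow(ing) < 2) {
    stop("reference set holds fewer than two members of group '", grp, "'",
         call. = FALSE)
  }
  seqs <- c(stats::setNames(candidate_seq, candidate_id),
            stats::setNames(ing$seq, ing$id),
            stats::setNames(refset$outgroup_seq, refset$outgroup_id))
  aln <- progressive_align(seqs, scoring)
  purrr::map_dfr(seq_along(methods), function(k) {
    m <- methods[k]
    st <- bootstrap_supports(aln, method = m, reps = reps,
                             seed = seed + (k - 1L))
    st <- root_at_outgroup(st, refset$outgroup_id)
    scc <- smallest_containing_clade(st, candidate_id)
    sis <- scc$sister
    if (length(sis) == 1 && sis %in% ing$id) {
      tibble(method = m, ortholog = sis,
             support = as.integer(scc$support),
             family = ing$family[match(sis, ing$id)],
             sister = list(sis))
    } else {
      tibble(method = m, ortholog = NA_character_,
             support = NA_integer_, family = NA_character_,
             sister = list(sis))
    }
  })
}

#' Assign a candidate from its per-method ingroup results
#'
#' Decision cascade over an ordered list of reference sets. Within a set:
#' (1) every method names the same ortholog with support at or above
#' `threshold` -- status `assigned`; (2) strictly more than `majority` of
#' the methods do -- `assigned_majority`; (3) at least one method names an
#' ortholog at any support -- `tentative`; (4) otherwise the next reference
#' set is consulted; when all are exhausted the candidate is
#' `lineage_specific`.
#'
#' @param results_by_refset Named list (in cascade order) of [ingroup_test()]
#'   tibbles.
#' @param threshold Support criterion (inclusive; default 50).
#' @param majority Fraction of methods in (0, 1); "more than half" = 0.5.
#' @return A one-row tibble: `status`, `family`, `ortholog`, `refset`,
#'   `best_support`, and `methods` (list column of the per-method results).
#' @export
assign_candidate <- function(results_by_refset, threshold = 50,
                             majority = 0.5) {
  if (!length(results_by_refset)) {
    stop("no ingroup results supplied", call. = FALSE)
  }
  if (is.null(names(results_by_refset))) {
    names(results_by_refset) <- paste0("refset", seq_along(results_by_refset))
  }
  for (nm in names(results_by_refset)) {
    res <- results_by_refset[[nm]]
    if (nrow(res) < 2) stop("need >= 2 methods per reference set",
                            call. = FALSE)
    named <- res[!is.na(res$ortholog), ]
    n_methods <- nrow(res)
    if (nrow(named) == n_methods &&
        length(unique(named$ortholog)) == 1 &&
        all(!is.na(named$support)) && all(named$support >= threshold)) {
      return(tibble(status = "assigned", family = named$family[1],
                    ortholog = named$ortholog[1], refset = nm,
                    best_support = max(named$support),
                    methods = list(res)))
    }
    strong <- named[!is.na(named$support) & named$support >= threshold, ]
    if (nrow(strong)) {
      tab <- sort(table(strong$ortholog), decreasing = TRUE)
      o <- names(tab)[1]
      if (tab[[1]] > majority * n_methods) {
        sel <- strong[strong$ortholog == o, ]
        return(tibble(status = "assigned_majority", family = sel$family[1],
                      ortholog = o, refset = nm,
                      best_support = max(sel$support),
                      methods = list(res)))
      }
    }
    if (nrow(named)) {
      best <- named[order(-dplyr::coalesce(named$support, -1L)), ][1, ]
      return(tibble(status = "tentative", family = best$family,
                    ortholog = best$ortholog, refset = nm,
                    best_support = best$support,
                    methods = list(res)))
    }
  }
  tibble(status = "lineage_specific", family = NA_character_,
         ortholog = NA_character_, refset = NA_character_,
         best_support = NA_integer_,
         methods = list(results_by_refset[[length(results_by_refset)]]))
}

#' Classify candidates against ordered reference sets
#'
#' For each candidate the putative family is the family of the reference
#' member with the highest global alignment score to the candidate (within
#' each reference set); the candidate is then run through [ingroup_test()]
#' and [assign_candidate()].
#'
#' @param candidates Tibble with `id` and `seq` (domain sequences).
#' @param refsets List of [reference_set()] objects in cascade order.
#' @param threshold,majority Cascade parameters, see [assign_candidate()].
#' @param methods,reps,seed,scoring,model Passed to [ingroup_test()].
#' @return A tibble of class `bhlh_assignments`: one row per candidate with
#'   the cascade outcome.
#' @export
classify_candidates <- function(candidates, refsets, threshold = 50,
                                majority = 0.5, methods = c("nj", "mp"),
                                reps = 1000, seed = 1000,
                                scoring = scoring_scheme(), model = "p") {
  if (is.null(names(refsets))) {
    names(refsets) <- vapply(refsets, function(r) r$label, character(1))
  }
  out <- purrr::map_dfr(seq_len(nrow(candidates)), function(i) {
    cid <- candidates$id[i]; cseq <- candidates$seq[i]
    results <- list()
    for (nm in names(refsets)) {
      rs <- refsets[[nm]]
      sc <- vapply(rs$members$seq, function(s)
        pairwise_global_align(cseq, s, scoring)$score, numeric(1))
      fam <- rs$members$family[which.max(sc)]
      grp <- rs$members$group[which.max(sc)]
      scope <- if (sum(rs$members$group == grp) >= 2) "group" else "all"
      results[[nm]] <- ingroup_test(cid, cseq, rs, fam, methods = methods,
                                    reps = reps, seed = seed + i,
                                    scoring = scoring, model = model,
                                    scope = scope)
    }
    a <- assign_candidate(results, threshold = threshold,
                          majority = majority)
    dplyr::bind_cols(tibble(id = cid), a)
  })
  class(out) <- c("bhlh_assignments", class(out))
  out
}

#' Name candidates after their ortholog families
#'
#' Single member of a family: species prefix plus the capitalized homolog
#' symbol. Multiple members: numeric suffixes 1..n ordered by descending
#' best support, ties by candidate id.
#'
#' @param assignments A [classify_candidates()] result (or compatible tibble
#'   with `id`, `family`, `ortholog`, `best_support`).
#' @param prefix Species prefix (for instance `"Nl"`).
#' @return A tibble `id`, `name`; candidates without a family keep their id
#'   (prefixed) as a provisional name.
#' @export
name_paralogs <- function(assignments, prefix = "Nl") {
  cap <- function(x) paste0(toupper(substr(x, 1, 1)), substr(x, 2, nchar(x)))
  df <- as_tibble(assignments)[, c("id", "family", "ortholog",
                                   "best_support")]
  out <- df %>%
    dplyr::group_by(.data$family) %>%
    dplyr::group_modify(function(d, key) {
      if (is.na(key$family)) {
        return(tibble(id = d$id, name = paste0(prefix, cap(d$id))))
      }
      base <- cap(d$ortholog[1])
      if (nrow(d) == 1) {
        return(tibble(id = d$id, name = paste0(prefix, base)))
      }
      ord <- order(-dplyr::coalesce(d$best_support, -1L), d$id)
      tibble(id = d$id[ord],
             name = paste0(prefix, base, seq_len(nrow(d))))
    }) %>%
    dplyr::ungroup()
  out[match(df$id, out$id), c("id", "name")]
}

#' Summarize an assignment table
#' @param x A `bhlh_assignments` tibble.
#' @param ... Unused.
#' @return A one-row tibble of per-status counts.
#' @export
glance.bhlh_assignments <- function(x, ...) {
  tibble(
    n = nrow(x),
    assigned = sum(x$status == "assigned"),
    assigned_majority = sum(x$status == "assigned_majority"),
    tentative = sum(x$status == "tentative"),
    lineage_specific = sum(x$status == "lineage_specific")
  )
}
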