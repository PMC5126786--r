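# Translated local search of genome scaffolds, locus extension/merging,
# candidate construction from gene models, redundancy removal and the
# candidate filter cascade.
#
# All genomic coordinates are 0-based half-open internally; GFF3 output is
# 1-based closed.

GENCODE <- NULL

gencode <- function() {
  if (is.null(GENCODE)) {
    gc <- Biostrings::GENETIC_CODE
    utils::assignInMyNamespace("GENCODE", gc)
  }
  GENCODE
}

revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

translate_nt <- function(seq) {
  n <- nchar(seq) %/% 3
  if (n == 0) return("")
  codons <- substring(seq, 3 * seq_len(n) - 2, 3 * seq_len(n))
  aa <- unname(gencode()[codons])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' Six-frame translation of a scaffold
#'
#' Translates the three forward and three reverse-complement frames with the
#' standard genetic code; stop codons become `*` and codons containing `N`
#' become `X`.
#'
#' @param seq Nucleotide sequence (string over `A,C,G,T,N`).
#' @return A tibble with `strand` (`+`/`-`), `frame` (0, 1, 2) and
#'   `protein`.
#' @export
six_frame_translate <- function(seq) {
  if (!nchar(seq)) stop("empty sequence", call. = FALSE)
  seq <- toupper(seq)
  if (grepl("[^ACGTN]", seq)) {
    stop("sequence contains letters outside {A,C,G,T,N}", call. = FALSE)
  }
  rc <- revcomp(seq)
  purrr::map_dfr(c("+", "-"), function(strand) {
    s <- if (strand == "+") seq else rc
    purrr::map_dfr(0:2, function(f) {
      tibble(strand = strand, frame = f,
             protein = translate_nt(substr(s, f + 1, nchar(s))))
    })
  })
}

#' Translated local search of scaffolds with a protein query
#'
#' Exact affine-gap local alignment (Smith-Waterman) of the query against
#' all six translated frames of each scaffold. Alignments never cross stop
#' codons or `N`-containing codons. Hit coordinates are reported on the
#' forward genomic strand.
#'
#' @param query Protein query (>= 10 residues).
#' @param scaffolds Named character vector of scaffold sequences, or a
#'   tibble with columns `id`, `seq`.
#' @param scoring A [scoring_scheme()]; gap penalties must be positive.
#' @param min_score Minimum alignment score of a reported hit.
#' @param query_id Identifier recorded with each hit.
#' @param max_hits_per_frame Cap on hits extracted per frame.
#' @param frames Optional precomputed [translate_scaffold_frames()]-style
#'   table, letting callers reuse one translation across many queries.
#' @return A tibble of hits: `scaffold_id`, `strand`, `frame`, `start`,
#'   `end` (0-based half-open genomic), `q_start`, `q_end`, `score`,
#'   `evalue_proxy`, `query_id`.
#' @export
translated_local_search <- function(query, scaffolds,
                                    scoring = scoring_scheme(),
                                    min_score = 40, query_id = "query",
                                    max_hits_per_frame = 25,
                                    frames = NULL) {
  if (nchar(query) < 10) stop("query must have >= 10 residues", call. = FALSE)
  if (scoring$gap_open <= 0 || scoring$gap_ext <= 0) {
    stop("gap penalties must be positive", call. = FALSE)
  }
  sc <- as_scaffold_tbl(scaffolds)
  if (is.null(frames)) frames <- translate_scaffold_frames(sc)
  qidx <- aa_encode(query)
  smat <- scoring$matrix[qidx, , drop = FALSE]
  # Karlin-Altschul-style proxy constants for gapped BLOSUM62 statistics
  lambda <- 0.267; K <- 0.041
  total_nt <- sum(nchar(sc$seq))
  out <- purrr::map_dfr(seq_len(nrow(frames)), function(fi) {
    subj <- frames$subj[[fi]]
    if (length(subj) < 5) return(NULL)
    hits <- sw_scan_cpp(smat, subj, scoring$gap_open, scoring$gap_ext,
                        min_score, as.integer(max_hits_per_frame))
    if (!length(hits)) return(NULL)
    f <- frames$frame[fi]
    L <- frames$scaffold_len[fi]
    purrr::map_dfr(hits, function(h) {
      if (frames$strand[fi] == "+") {
        gs <- f + 3 * (h$s_start - 1)
        ge <- f + 3 * h$s_end
      } else {
        gs <- L - (f + 3 * h$s_end)
        ge <- L - (f + 3 * (h$s_start - 1))
      }
      tibble(scaffold_id = frames$scaffold_id[fi],
             strand = frames$strand[fi],
             frame = f, start = as.integer(gs), end = as.integer(ge),
             q_start = h$q_start - 1L, q_end = as.integer(h$q_end),
             score = h$score,
             evalue_proxy = K * nchar(query) * (total_nt / 3) *
               exp(-lambda * h$score),
             query_id = query_id)
    })
  })
  if (nrow(out)) out <- dplyr::arrange(out, .data$scaffold_id, .data$start)
  out
}

# six-frame translate and integer-encode every scaffold once; reused across
# queries
translate_scaffold_frames <- function(sc) {
  purrr::map_dfr(seq_len(nrow(sc)), function(si) {
    seq <- toupper(sc$seq[si])
    fr <- six_frame_translate(seq)
    fr$scaffold_id <- sc$id[si]
    fr$scaffold_len <- nchar(seq)
    fr$subj <- lapply(fr$protein, aa_encode, allow_x = TRUE)
    fr$protein <- NULL
    fr
  })
}

as_scaffold_tbl <- function(scaffolds) {
  if (is.data.frame(scaffolds)) {
    stopifnot(all(c("id", "seq") %in% names(scaffolds)))
    return(as_tibble(scaffolds[, c("id", "seq")]))
  }
  if (inherits(scaffolds, "DNAStringSet")) {
    return(tibble(id = names(scaffolds), seq = as.character(scaffolds)))
  }
  stopifnot(is.character(scaffolds), !is.null(names(scaffolds)))
  tibble(id = names(scaffolds), seq = unname(scaffolds))
}

#' Read scaffolds from a FASTA file
#' @param path FASTA file of nucleotide scaffolds.
#' @return A tibble with `id` and `seq`.
#' @export
read_scaffolds <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  tibble(id = sub("\\s.*$", "", names(x)), seq = as.character(x))
}

#' Extend search hits and merge them into candidate loci
#'
#' Each hit interval is extended by `flank` base pairs on both sides
#' (clamped to the scaffold), and overlapping or touching extended intervals
#' on the same scaffold are merged.
#'
#' @param hits A [translated_local_search()] hit tibble.
#' @param flank Extension in bp (default 10,000).
#' @param scaffold_lengths Named integer vector of scaffold lengths.
#' @return A tibble of loci: `locus_id`, `scaffold_id`, `start`, `end`,
#'   `n_hits`.
#' @export
extend_and_merge <- function(hits, flank = 10000, scaffold_lengths) {
  stopifnot(flank >= 0)
  if (nrow(hits) == 0) {
    return(tibble(locus_id = character(), scaffold_id = character(),
                  start = integer(), end = integer(), n_hits = integer()))
  }
  unknown <- setdiff(unique(hits$scaffold_id), names(scaffold_lengths))
  if (length(unknown)) {
    stop("hit(s) reference unknown scaffold(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  res <- hits %>%
    dplyr::group_by(.data$scaffold_id) %>%
    dplyr::group_modify(function(d, key) {
      len <- scaffold_lengths[[key$scaffold_id]]
      s <- pmax(d$start - flank, 0)
      e <- pmin(d$end + flank, len)
      ir <- IRanges::IRanges(start = s + 1, end = e)
      red <- IRanges::reduce(ir)
      ov <- IRanges::countOverlaps(red, ir)
      tibble(start = as.integer(IRanges::start(red) - 1L),
             end = as.integer(IRanges::end(red)),
             n_hits = as.integer(ov))
    }) %>%
    dplyr::ungroup() %>%
    dplyr::arrange(.data$scaffold_id, .data$start)
  res$locus_id <- sprintf("locus%03d", seq_len(nrow(res)))
  res[, c("locus_id", "scaffold_id", "start", "end", "n_hits")]
}

# ---- gene models ------------------------------------------------------------

#' Construct a gene model
#'
#' @param gene_id Identifier.
#' @param scaffold_id Scaffold the gene lies on.
#' @param strand `"+"` or `"-"`.
#' @param exons A data frame with `start`, `end` (0-based half-open genomic
#'   coordinates), rows ordered in transcription direction. The total CDS
#'   length must be divisible by 3.
#' @return A one-row tibble with an `exons` list column.
#' @export
gene_model <- function(gene_id, scaffold_id, strand, exons) {
  exons <- as_tibble(exons[, c("start", "end")])
  genomic_order <- if (strand == "+") exons$start else rev(exons$start)
  if (is.unsorted(genomic_order, strictly = TRUE) && nrow(exons) > 1) {
    stop("exons must be ordered in transcription direction", call. = FALSE)
  }
  so <- sort(exons$start)
  eo <- sort(exons$end)
  if (nrow(exons) > 1 && any(so[-1] < eo[-nrow(exons)])) {
    stop("exons overlap", call. = FALSE)
  }
  if (sum(exons$end - exons$start) %% 3 != 0) {
    stop("total CDS length must be divisible by 3", call. = FALSE)
  }
  tibble(gene_id = gene_id, scaffold_id = scaffold_id, strand = strand,
         exons = list(exons))
}

# spliced CDS nucleotide sequence of a model on its scaffold
spliced_cds <- function(model, scaffold_seq) {
  ex <- model$exons[[1]]
  parts <- substring(scaffold_seq, ex$start + 1, ex$end)
  if (model$strand == "-") parts <- vapply(parts, revcomp, character(1))
  paste(parts, collapse = "")
}

#' Conceptual translation of a gene model
#' @param model One-row gene model tibble.
#' @param scaffold_seq The scaffold sequence the model refers to.
#' @return The protein string (trailing stop removed).
#' @export
model_protein <- function(model, scaffold_seq) {
  p <- translate_nt(spliced_cds(model, scaffold_seq))
  sub("\\*$", "", p)
}

# reading frame of the CDS relative to the forward scaffold coordinates
model_frame <- function(model, scaffold_len) {
  ex <- model$exons[[1]]
  if (model$strand == "+") min(ex$start) %% 3
  else (scaffold_len - max(ex$end)) %% 3
}

#' Read / write gene models as GFF3
#'
#' Models are stored as `gene` + `CDS` features; coordinates are converted
#' between the internal 0-based half-open and GFF3 1-based closed
#' conventions.
#'
#' @param path GFF3 file path.
#' @return `read_gene_models()` returns a gene-model tibble.
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  cds <- gr[gr$type == "CDS"]
  parents <- vapply(cds$Parent, function(p) p[[1]], character(1))
  ids <- unique(parents)
  purrr::map_dfr(ids, function(g) {
    sub <- cds[parents == g]
    strand <- as.character(BiocGenerics::strand(sub))[1]
    st <- BiocGenerics::start(sub) - 1L
    en <- BiocGenerics::end(sub)
    o <- order(st)
    if (strand == "-") o <- rev(o)
    gene_model(g, as.character(GenomeInfoDb::seqnames(sub))[1], strand,
               tibble(start = st[o], end = en[o]))
  })
}

#' @rdname read_gene_models
#' @param models Gene-model tibble.
#' @export
write_gene_models <- function(models, path) {
  lines <- c("##gff-version 3")
  for (i in seq_len(nrow(models))) {
    m <- models[i, ]
    ex <- m$exons[[1]]
    g0 <- min(ex$start); g1 <- max(ex$end)
    lines <- c(lines, paste(m$scaffold_id, "bhlhscan", "gene", g0 + 1, g1,
                            ".", m$strand, ".",
                            paste0("ID=", m$gene_id), sep = "\t"))
    ord <- order(ex$start)
    for (k in ord) {
      lines <- c(lines, paste(m$scaffold_id, "bhlhscan", "CDS",
                              ex$start[k] + 1, ex$end[k], ".", m$strand,
                              ".", paste0("ID=", m$gene_id, ".cds", k,
                                          ";Parent=", m$gene_id),
                              sep = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Build candidate genes from loci and gene models
#'
#' Gene models whose genomic extent overlaps a candidate locus on the same
#' scaffold become candidate genes, carrying their conceptual translation.
#'
#' @param loci An [extend_and_merge()] locus tibble.
#' @param models A gene-model tibble.
#' @param scaffolds Scaffold tibble (`id`, `seq`).
#' @return A candidate tibble: gene model columns plus `frame`, `protein`,
#'   `locus_id`, `cds_len`.
#' @export
candidates_from_loci <- function(loci, models, scaffolds) {
  sc <- as_scaffold_tbl(scaffolds)
  out <- purrr::map_dfr(seq_len(nrow(models)), function(i) {
    m <- models[i, ]
    ex <- m$exons[[1]]
    g0 <- min(ex$start); g1 <- max(ex$end)
    hit <- loci$scaffold_id == m$scaffold_id &
      loci$start < g1 & loci$end > g0
    if (!any(hit)) return(NULL)
    seq <- sc$seq[match(m$scaffold_id, sc$id)]
    m$frame <- model_frame(m, nchar(seq))
    m$protein <- model_protein(m, seq)
    m$cds_len <- sum(ex$end - ex$start)
    m$locus_id <- loci$locus_id[which(hit)[1]]
    m
  })
  out
}

# ---- redundancy removal -----------------------------------------------------

reciprocal_overlap <- function(ex_a, ex_b) {
  ia <- IRanges::IRanges(ex_a$start + 1, ex_a$end)
  ib <- IRanges::IRanges(ex_b$start + 1, ex_b$end)
  ov <- sum(IRanges::width(IRanges::intersect(ia, ib)))
  c(ov / sum(IRanges::width(ia)), ov / sum(IRanges::width(ib)))
}

#' Collapse redundant candidate genes
#'
#' Candidates on the same scaffold with the same strand and reading frame
#' whose coding regions overlap reciprocally by at least
#' `min_reciprocal_overlap` collapse to one representative: the longest CDS,
#' ties broken by leftmost start. The operation is idempotent.
#'
#' @param candidates A candidate tibble (needs `gene_id`, `scaffold_id`,
#'   `strand`, `frame`, `exons`, `cds_len`).
#' @param min_reciprocal_overlap Fraction in (0, 1].
#' @return A list with `candidates` (kept rows) and `audit` (dropped rows:
#'   `gene_id`, `kept_as`, `overlap`).
#' @export
deduplicate_candidates <- function(candidates, min_reciprocal_overlap = 0.8) {
  stopifnot(min_reciprocal_overlap > 0, min_reciprocal_overlap <= 1)
  n <- nrow(candidates)
  if (n <= 1) {
    return(list(candidates = candidates,
                audit = tibble(gene_id = character(), kept_as = character(),
                               overlap = numeric())))
  }
  if (!"cds_len" %in% names(candidates)) {
    candidates$cds_len <- vapply(candidates$exons,
                                 function(e) sum(e$end - e$start), numeric(1))
  }
  # union-find over redundant pairs
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  ovmat <- rep(NA_real_, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (candidates$scaffold_id[i] != candidates$scaffold_id[j]) next
      if (candidates$strand[i] != candidates$strand[j]) next
      if (candidates$frame[i] != candidates$frame[j]) next
      ro <- reciprocal_overlap(candidates$exons[[i]], candidates$exons[[j]])
      if (min(ro) >= min_reciprocal_overlap) {
        parent[find(i)] <- find(j)
        ovmat[j] <- min(ro)
      }
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  keep <- logical(n)
  kept_as <- character(n)
  for (g in unique(comp)) {
    idx <- which(comp == g)
    starts <- vapply(candidates$exons[idx], function(e) min(e$start),
                     numeric(1))
    best <- idx[order(-candidates$cds_len[idx], starts)][1]
    keep[best] <- TRUE
    kept_as[idx] <- candidates$gene_id[best]
  }
  list(candidates = candidates[keep, ],
       audit = tibble(gene_id = candidates$gene_id[!keep],
                      kept_as = kept_as[!keep],
                      overlap = ovmat[!keep]))
}

#' Candidate filter cascade
#'
#' Applies the acceptance filters in order -- domain hit present,
#' conserved-site validation, redundancy removal -- recording a full audit
#' trail for every candidate.
#'
#' @param candidates Candidate tibble with `gene_id` and `protein`.
#' @param profile A [build_motif_profile()].
#' @param scheme A [region_scheme()].
#' @param site_table A [conserved_site_table()].
#' @param scoring A [scoring_scheme()].
#' @param min_motif_score Minimum profile alignment score.
#' @param min_reciprocal_overlap Redundancy threshold.
#' @return A list with `accepted` (candidates carrying a `motif_hit` list
#'   column) and `audit` (tibble of `gene_id`, `stage`, `pass`, `reason`).
#' @export
candidate_filter_cascade <- function(candidates, profile,
                                     scheme = region_scheme(),
                                     site_table = default_site_table(),
                                     scoring = scoring_scheme(),
                                     min_motif_score = 60,
                                     min_reciprocal_overlap = 0.8) {
  audit <- tibble(gene_id = character(), stage = character(),
                  pass = logical(), reason = character())
  if (nrow(candidates) == 0) {
    return(list(accepted = candidates, audit = audit))
  }
  log_stage <- function(gene_id, stage, pass, reason) {
    audit <<- dplyr::bind_rows(audit, tibble(gene_id = gene_id,
                                             stage = stage, pass = pass,
                                             reason = reason))
  }
  hits <- vector("list", nrow(candidates))
  ok <- logical(nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    gid <- candidates$gene_id[i]
    h <- scan_protein(candidates$protein[i], profile, scheme, site_table,
                      protein_id = gid, scoring = scoring,
                      min_score = min_motif_score)
    if (nrow(h) == 0) {
      log_stage(gid, "motif_hit", FALSE, "no_motif")
      next
    }
    log_stage(gid, "motif_hit", TRUE, "")
    hp <- h[h$pass, ]
    if (nrow(hp) == 0) {
      log_stage(gid, "conserved_sites", FALSE,
                sprintf("best_matches=%d", max(h$site_matches)))
      next
    }
    log_stage(gid, "conserved_sites", TRUE, "")
    hits[[i]] <- hp[which.max(hp$score), ]
    ok[i] <- TRUE
  }
  surv <- candidates[ok, ]
  surv$motif_hit <- hits[ok]
  if (nrow(surv) > 1 && all(c("scaffold_id", "strand", "frame") %in%
                            names(surv))) {
    dd <- deduplicate_candidates(surv,
                                 min_reciprocal_overlap = min_reciprocal_overlap)
    if (nrow(dd$audit)) {
      log_stage(dd$audit$gene_id, "redundancy", FALSE,
                paste0("duplicate_of=", dd$audit$kept_as))
    }
    if (nrow(dd$candidates)) {
      log_stage(dd$candidates$gene_id, "redundancy", TRUE, "")
    }
    surv <- dd$candidates
  } else if (nrow(surv)) {
    log_stage(surv$gene_id, "redundancy", TRUE, "")
  }
  list(accepted = surv, audit = audit)
}
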