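#' Per-genome VFam / ANN-Pfam co-domain counts
#'
#' Intersects VFam hits (endogenous viral-element signatures) with Pfam
#' hits at the ORF level: a co-domain ORF carries at least one VFam hit and
#' at least one hit to a Pfam from the classifier's discriminant set. Both
#' hit lists are expected to be E-value filtered (1e-9) already; rows are
#' deduplicated on genome + ORF + model + coordinates before counting.
#'
#' @param pfam_hits,vfam_hits Hit data frames (see [parse_domtblout()]).
#' @param ann_pfams Non-empty character vector of discriminant Pfam
#'   accessions.
#' @param labels Optional named `"HL"`/`"LL"` vector over genome ids.
#' @return Data frame with one row per genome appearing in `vfam_hits`:
#'   `genome_id`, `label`, `n_vfam_orfs` (ORFs with >= 1 VFam hit),
#'   `n_codomain_orfs` (of those, ORFs also bearing an ANN Pfam),
#'   `n_vfam_on_ann_orfs` (VFam hit rows on such ORFs).
#' @export
codomain_counts <- function(pfam_hits, vfam_hits, ann_pfams, labels = NULL) {
  stopifnot(length(ann_pfams) > 0L)
  pfam_hits <- dedup_hits(pfam_hits)
  vfam_hits <- dedup_hits(vfam_hits)

  both <- intersect(unique(vfam_hits$genome_id), unique(pfam_hits$genome_id))
  if (length(both) > 0L) {
    shared <- intersect(
      unique(paste(vfam_hits$genome_id, vfam_hits$orf_id)),
      unique(paste(pfam_hits$genome_id, pfam_hits$orf_id)))
    if (length(shared) == 0L) {
      warning("no ORF ids shared between Pfam and VFam hits; ",
              "protein sets may be mismatched")
    }
  }

  ann_orfs <- unique(paste(pfam_hits$genome_id, pfam_hits$orf_id)[
    pfam_hits$model_acc %in% ann_pfams])

  genomes <- unique(vfam_hits$genome_id)
  rows <- lapply(genomes, function(g) {
    vh <- vfam_hits[vfam_hits$genome_id == g, , drop = FALSE]
    orfs <- unique(vh$orf_id)
    co <- orfs[paste(g, orfs) %in% ann_orfs]
    data.frame(genome_id = g,
               label = if (is.null(labels)) NA_character_ else labels[[g]],
               n_vfam_orfs = length(orfs),
               n_codomain_orfs = length(co),
               n_vfam_on_ann_orfs = sum(vh$orf_id %in% co),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' HL vs LL group difference in co-domain counts
#'
#' Welch two-tailed t-test on a chosen count field between the LL and HL
#' genomes; the mean difference is reported as LL minus HL, so a positive
#' difference means the low-light strains carry more of the counted
#' signature.
#'
#' @param counts Data frame from [codomain_counts()] with `label` filled.
#' @param field Count column to test (default `"n_vfam_on_ann_orfs"`).
#' @return List with `mean_hl`, `mean_ll`, `mean_diff` (LL - HL),
#'   `t_ratio`, `df`, `p_two_tailed`.
#' @export
group_difference <- function(counts, field = "n_vfam_on_ann_orfs") {
  stopifnot(field %in% names(counts))
  hl <- counts[[field]][counts$label == "HL"]
  ll <- counts[[field]][counts$label == "LL"]
  if (length(hl) < 2L || length(ll) < 2L) {
    stop("each group needs n >= 2", call. = FALSE)
  }
  w <- welch_stats(ll, hl)
  if (w$se == 0) {
    t_ratio <- 0
    p <- if (w$diff == 0) 1 else 0
  } else {
    t_ratio <- w$diff / w$se
    p <- 2 * stats::pt(-abs(t_ratio), w$df)
  }
  list(mean_hl = mean(hl), mean_ll = mean(ll), mean_diff = w$diff,
       t_ratio = t_ratio, df = w$df, p_two_tailed = p)
}
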