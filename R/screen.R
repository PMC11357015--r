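# Welch statistics shared by the screen's t constructions
welch_stats <- function(a, b) {
  na <- length(a); nb <- length(b)
  va <- stats::var(a); vb <- stats::var(b)
  se2 <- va / na + vb / nb
  df <- if (se2 > 0) {
    se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  } else {
    na + nb - 2
  }
  list(diff = mean(a) - mean(b), se = sqrt(se2), df = df)
}

#' Two one-sided tests (TOST) of practical equivalence
#'
#' Tests whether the group-mean difference lies confidently inside
#' `(-delta, +delta)`. Two one-sided Welch t-tests are run against the null
#' hypotheses that the true difference exceeds `+delta` or falls below
#' `-delta`; the equivalence p-value is the larger of the two one-sided
#' p-values, so equivalence is declared only when both nulls are rejected.
#'
#' @param a,b Numeric vectors (each length >= 2).
#' @param delta Non-negative equivalence margin on the scale of the data.
#' @return The equivalence p-value in `[0, 1]`.
#' @export
tost_equivalence <- function(a, b, delta) {
  stopifnot(length(a) >= 2L, length(b) >= 2L, delta >= 0)
  w <- welch_stats(a, b)
  if (w$se == 0) {
    # no within-group spread at all: equivalence is decided by geometry
    return(if (abs(w$diff) < delta) 0 else 1)
  }
  p_upper <- stats::pt((w$diff - delta) / w$se, w$df)              # H0: diff >= +delta
  p_lower <- stats::pt((w$diff + delta) / w$se, w$df, lower.tail = FALSE) # H0: diff <= -delta
  max(p_upper, p_lower)
}

#' Robust screen of one feature: difference, practical difference, TOST
#'
#' Single-feature building block of the response screen. Observations in
#' each group are Huber-reweighted into pseudo-observations (outlier
#' correction), then compared with Welch t machinery: a two-sided test of
#' any difference, a one-sided test of whether |difference| exceeds the
#' practical-difference threshold `6 * 0.10 * sigma_hat`
#' (`sigma_hat = IQR/1.3489795` on the pooled raw values), and a TOST
#' equivalence test at that same threshold. The trichotomous call is
#' `practical_difference` when the practical-difference test rejects at
#' `alpha`, else `practical_equivalence` when the TOST rejects, else
#' `inconclusive`.
#'
#' @param hl,ll Numeric vectors of feature values in the two groups
#'   (each length >= 2).
#' @param alpha Significance level for the call trichotomy (default 0.05).
#' @param pd_proportion Practical-difference proportion (default 0.10).
#' @param k Huber tuning constant.
#' @return One-row data frame with `mean_hl`, `mean_ll`, `mean_diff`,
#'   `p_value`, `logworth`, `sigma_hat`, `practical_difference`,
#'   `p_practical_diff`, `p_equivalence`, `call`.
#' @export
screen_feature <- function(hl, ll, alpha = 0.05, pd_proportion = 0.10, k = 1.345) {
  stopifnot(length(hl) >= 2L, length(ll) >= 2L)
  ph <- huber_pseudo_obs(hl, k = k)
  pl <- huber_pseudo_obs(ll, k = k)
  w <- welch_stats(ph, pl)

  sigma_hat <- robust_sigma(c(hl, ll))
  pd <- practical_difference_threshold(sigma_hat, pd_proportion)

  if (w$se == 0) {
    p_value <- if (w$diff == 0) 1 else 0
    p_pd <- if (abs(w$diff) > pd) 0 else 1
  } else {
    p_value <- 2 * stats::pt(-abs(w$diff) / w$se, w$df)
    # H0: |diff| <= pd vs |diff| > pd, assessed at the boundary
    p_pd <- stats::pt((abs(w$diff) - pd) / w$se, w$df, lower.tail = FALSE)
  }
  p_eq <- tost_equivalence(ph, pl, pd)

  call <- if (p_pd < alpha) {
    "practical_difference"
  } else if (p_eq < alpha) {
    "practical_equivalence"
  } else {
    "inconclusive"
  }
  data.frame(
    mean_hl = mean(ph), mean_ll = mean(pl), mean_diff = w$diff,
    p_value = p_value, logworth = -log10(p_value),
    sigma_hat = sigma_hat, practical_difference = pd,
    p_practical_diff = p_pd, p_equivalence = p_eq,
    call = call, stringsAsFactors = FALSE
  )
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values controlling the false discovery rate across a
#' batch of tests (wraps [stats::p.adjust()] with `method = "BH"` after
#' validating the input range).
#'
#' @param p_values Numeric vector, all in `[0, 1]`.
#' @return Adjusted p-values, each >= its raw p.
#' @export
fdr_adjust <- function(p_values) {
  if (length(p_values) == 0L) return(numeric())
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Response screen of every domain family in a matrix
#'
#' Runs [screen_feature()] on each column of a labeled genomes x models
#' matrix (HL vs LL) and applies Benjamini-Hochberg FDR adjustment across
#' the batch. This is the FDR- and outlier-corrected batch comparison that
#' ranks domain families by how strongly they separate the two light
#' ecotypes.
#'
#' @param m A `domain_matrix` carrying `"HL"`/`"LL"` labels, each group with
#'   at least two genomes.
#' @param alpha Significance level for the per-feature call trichotomy.
#' @param pd_proportion Practical-difference proportion.
#' @param k Huber tuning constant.
#' @return A `response_screen` object: a data frame with one row per model
#'   accession (columns of [screen_feature()] plus `model_acc`, `fdr_p`,
#'   `fdr_logworth`), with attributes recording `alpha` and group sizes.
#' @export
response_screen <- function(m, alpha = 0.05, pd_proportion = 0.10, k = 1.345) {
  stopifnot(inherits(m, "domain_matrix"))
  labels <- matrix_labels(m)
  if (is.null(labels)) stop("matrix has no HL/LL labels", call. = FALSE)
  hl_rows <- labels == "HL"
  ll_rows <- labels == "LL"
  if (sum(hl_rows) < 2L || sum(ll_rows) < 2L) {
    stop("each group needs at least two genomes", call. = FALSE)
  }
  if (ncol(m) == 0L) {
    out <- data.frame(model_acc = character(), mean_hl = numeric(),
                      mean_ll = numeric(), mean_diff = numeric(),
                      p_value = numeric(), logworth = numeric(),
                      fdr_p = numeric(), fdr_logworth = numeric(),
                      sigma_hat = numeric(), practical_difference = numeric(),
                      p_practical_diff = numeric(), p_equivalence = numeric(),
                      call = character(), stringsAsFactors = FALSE)
  } else {
    rows <- lapply(seq_len(ncol(m)), function(j) {
      screen_feature(m[hl_rows, j], m[ll_rows, j], alpha = alpha,
                     pd_proportion = pd_proportion, k = k)
    })
    out <- do.call(rbind, rows)
    out <- cbind(data.frame(model_acc = colnames(m), stringsAsFactors = FALSE), out)
    out$fdr_p <- fdr_adjust(out$p_value)
    out$fdr_logworth <- -log10(out$fdr_p)
    out <- out[, c("model_acc", "mean_hl", "mean_ll", "mean_diff", "p_value",
                   "logworth", "fdr_p", "fdr_logworth", "sigma_hat",
                   "practical_difference", "p_practical_diff", "p_equivalence",
                   "call")]
  }
  structure(out, class = c("response_screen", "data.frame"),
            alpha = alpha, n_hl = sum(hl_rows), n_ll = sum(ll_rows))
}

#' Rank screened features
#'
#' Orders a screen by FDR p-value, breaking ties by |mean difference|
#' (descending) and then model accession, so top-k selections are
#' reproducible.
#'
#' @param x A `response_screen`.
#' @param k Number of features to return (default all).
#' @return The top-k rows of the screen in rank order.
#' @export
top_features <- function(x, k = nrow(x)) {
  stopifnot(inherits(x, "response_screen"))
  ord <- order(x$fdr_p, -abs(x$mean_diff), x$model_acc)
  out <- x[ord, , drop = FALSE]
  utils::head(out, k)
}

#' @export
print.response_screen <- function(x, ...) {
  cat(sprintf("response_screen: %d features, %d HL vs %d LL genomes (alpha = %g)\n",
              nrow(x), attr(x, "n_hl"), attr(x, "n_ll"), attr(x, "alpha")))
  print(table(call = x$call))
  invisible(x)
}

#' @export
summary.response_screen <- function(object, k = 10L, ...) {
  cat(sprintf("Top %d features by FDR p-value:\n", min(k, nrow(object))))
  top <- top_features(object, k)
  print(data.frame(model_acc = top$model_acc,
                   mean_diff = signif(top$mean_diff, 4),
                   fdr_p = signif(top$fdr_p, 3),
                   call = top$call, row.names = NULL))
  invisible(top)
}
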