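#' Load a pfam2go mapping
#'
#' Parses the GO-consortium pfam2go flat-file dialect:
#' `Pfam:PF00288 GHMP_kinases_N > GO:phosphorylation ; GO:0016310`
#' with `!` comment lines. Duplicate mappings collapse to a set.
#'
#' @param con File path, connection, or character vector of lines.
#' @return Named list mapping Pfam accession to a character vector of GO
#'   ids; attribute `go_names` maps GO id to term name.
#' @export
load_pfam2go <- function(con) {
  lines <- if (is.character(con) && length(con) == 1L && file.exists(con)) {
    readLines(con, warn = FALSE)
  } else if (is.character(con)) con else readLines(con, warn = FALSE)
  keep <- which(!grepl("^!", lines) & nzchar(trimws(lines)))
  mapping <- list()
  go_names <- character()
  for (i in keep) {
    m <- regmatches(lines[i],
      regexec("^Pfam:(PF\\d+)[^>]*>\\s*GO:(.*?)\\s*;\\s*(GO:\\d+)\\s*$", lines[i]))[[1L]]
    if (length(m) != 4L) {
      stop("malformed pfam2go line ", i, ": ", lines[i], call. = FALSE)
    }
    acc <- m[2L]; go_id <- m[4L]
    mapping[[acc]] <- union(mapping[[acc]], go_id)
    go_names[go_id] <- m[3L]
  }
  structure(mapping, go_names = go_names)
}

#' Domain-centric GO enrichment of a Pfam set
#'
#' For every GO term reachable from the background through the pfam2go
#' mapping, computes the hypergeometric upper-tail probability of seeing at
#' least `k` annotated Pfams in a set of size `n` drawn from a background of
#' `N` Pfams of which `K` are annotated, together with the
#' normal-approximation Z-score
#' `(k - nK/N) / sqrt(nK/N (1 - K/N)(N - n)/(N - 1))`, and adjusts across
#' terms with Benjamini-Hochberg.
#'
#' @param pfam_set Character vector of Pfam accessions (the foreground);
#'   must be a subset of `background`.
#' @param background Character vector of all Pfam accessions considered.
#' @param mapping A [load_pfam2go()] mapping.
#' @return Data frame sorted by p-value with columns `go_id`, `go_name`,
#'   `k`, `K`, `n`, `N`, `p_value`, `z_score`, `fdr_p`.
#' @export
enrich_pfam_go <- function(pfam_set, background, mapping) {
  pfam_set <- unique(pfam_set)
  background <- unique(background)
  stopifnot(length(pfam_set) > 0L, length(background) > 0L)
  if (!all(pfam_set %in% background)) {
    stop("pfam_set must be a subset of the background", call. = FALSE)
  }
  bg_map <- mapping[intersect(names(mapping), background)]
  terms <- sort(unique(unlist(bg_map, use.names = FALSE)))
  if (length(terms) == 0L) {
    return(data.frame(go_id = character(), go_name = character(),
                      k = integer(), K = integer(), n = integer(),
                      N = integer(), p_value = numeric(), z_score = numeric(),
                      fdr_p = numeric(), stringsAsFactors = FALSE))
  }
  n <- length(pfam_set)
  N <- length(background)
  go_names <- attr(mapping, "go_names")
  rows <- lapply(terms, function(term) {
    annotated <- names(bg_map)[vapply(bg_map, function(g) term %in% g, logical(1L))]
    K <- length(annotated)
    k <- length(intersect(annotated, pfam_set))
    p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    ex <- n * K / N
    vr <- ex * (1 - K / N) * (N - n) / (N - 1)
    z <- if (vr > 0) (k - ex) / sqrt(vr) else 0
    data.frame(go_id = term,
               go_name = if (term %in% names(go_names)) go_names[[term]] else NA_character_,
               k = k, K = K, n = n, N = N, p_value = p, z_score = z,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr_p <- fdr_adjust(out$p_value)
  out[order(out$p_value, out$go_id), , drop = FALSE]
}
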