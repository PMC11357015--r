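#' Assemble a genomes x models sum-bit-score matrix
#'
#' Each cell is the sum of the chosen score field over all hits of that model
#' in that genome; a model absent from a genome contributes 0. Genomes listed
#' in `genome_ids` but absent from `hits` get all-zero rows, so the matrix
#' always covers the full genome panel.
#'
#' @param hits Hit data frame (see [parse_domtblout()]), usually already
#'   E-value filtered with [filter_hits()].
#' @param genome_ids Ordered character vector of all genomes in the panel.
#'   Every hit's `genome_id` must appear here.
#' @param score_field `"full_seq_bitscore"` (default, the per-sequence score
#'   summed per model) or `"domain_bitscore"`.
#' @param labels Optional named character vector mapping genome ids to
#'   `"HL"`/`"LL"` group labels.
#' @return A `domain_matrix`: numeric matrix (rows = genomes, cols = model
#'   accessions) with attributes `normalization = "raw_sum"` and `labels`.
#' @export
build_matrix <- function(hits, genome_ids,
                         score_field = c("full_seq_bitscore", "domain_bitscore"),
                         labels = NULL) {
  score_field <- match.arg(score_field)
  stopifnot(!anyDuplicated(genome_ids))
  unknown <- setdiff(unique(hits$genome_id), genome_ids)
  if (length(unknown) > 0L) {
    stop("hits reference genome ids not in the panel: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  model_accs <- sort(unique(hits$model_acc))
  m <- matrix(0, nrow = length(genome_ids), ncol = length(model_accs),
              dimnames = list(genome_ids, model_accs))
  if (nrow(hits) > 0L) {
    agg <- tapply(hits[[score_field]],
                  list(factor(hits$genome_id, levels = genome_ids),
                       factor(hits$model_acc, levels = model_accs)),
                  sum)
    agg[is.na(agg)] <- 0
    m[] <- agg
  }
  domain_matrix(m, normalization = "raw_sum", labels = labels)
}

#' Construct a domain_matrix from a plain matrix
#'
#' @param values Non-negative numeric matrix, genomes as rows (rownames) and
#'   model accessions as columns (colnames).
#' @param normalization One of `"raw_sum"`, `"per_genome_rate"`, `"none"`.
#' @param labels Optional named `"HL"`/`"LL"` vector over the genomes.
#' @return A `domain_matrix` object.
#' @export
domain_matrix <- function(values, normalization = c("raw_sum", "per_genome_rate", "none"),
                          labels = NULL) {
  normalization <- match.arg(normalization)
  stopifnot(is.matrix(values), is.numeric(values),
            nrow(values) == 0L || !is.null(rownames(values)),
            ncol(values) == 0L || !is.null(colnames(values)),
            !anyDuplicated(rownames(values)), !anyDuplicated(colnames(values)),
            !anyNA(values))
  if (!is.null(labels)) {
    labels <- labels[rownames(values)]
    if (anyNA(labels) || !all(labels %in% c("HL", "LL"))) {
      stop("labels must map every genome id to 'HL' or 'LL'", call. = FALSE)
    }
  }
  structure(values, class = c("domain_matrix", "matrix", "array"),
            normalization = normalization, labels = labels)
}

#' @export
print.domain_matrix <- function(x, ...) {
  lab <- attr(x, "labels")
  cat(sprintf("domain_matrix: %d genomes x %d models (%s%s)\n",
              nrow(x), ncol(x), attr(x, "normalization"),
              if (is.null(lab)) "" else
                sprintf("; %d HL / %d LL", sum(lab == "HL"), sum(lab == "LL"))))
  print(utils::head(unclass(x)[, seq_len(min(5L, ncol(x))), drop = FALSE]))
  invisible(x)
}

#' Per-genome rate normalization of a raw sum-bit-score matrix
#'
#' Divides each genome row by its total and rescales to a fixed constant, so
#' cells become comparable rates that are free of genome-size and
#' annotation-depth effects. All-zero rows pass through unchanged.
#'
#' @param m A `domain_matrix` with `normalization = "raw_sum"` and
#'   non-negative values.
#' @param scale Row total after normalization (default 1000).
#' @return A `domain_matrix` with `normalization = "per_genome_rate"`.
#' @export
normalize_matrix <- function(m, scale = 1000) {
  stopifnot(inherits(m, "domain_matrix"), scale > 0)
  if (attr(m, "normalization") != "raw_sum") {
    stop("normalize_matrix expects a raw_sum matrix", call. = FALSE)
  }
  if (any(m < 0)) stop("negative values in raw sum matrix", call. = FALSE)
  tot <- rowSums(m)
  v <- unclass(m)
  nz <- tot > 0
  v[nz, ] <- v[nz, , drop = FALSE] / tot[nz] * scale
  domain_matrix(v, normalization = "per_genome_rate", labels = attr(m, "labels"))
}

#' Write / read a domain matrix as TSV
#'
#' The TSV has genomes as rows, a leading `genome_id` column, and one column
#' per model accession. `read_matrix_tsv()` restores labels from an optional
#' two-column (genome_id, label) TSV.
#'
#' @param m A `domain_matrix`.
#' @param path Output TSV path.
#' @return `write_matrix_tsv()`: the path, invisibly. `read_matrix_tsv()`:
#'   a `domain_matrix`.
#' @export
write_matrix_tsv <- function(m, path) {
  df <- data.frame(genome_id = rownames(m), unclass(m), check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @param labels_path Optional labels TSV (columns genome_id, label).
#' @param normalization Normalization tag to attach on read.
#' @export
read_matrix_tsv <- function(path, labels_path = NULL, normalization = "none") {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  v <- as.matrix(df[, -1L, drop = FALSE])
  rownames(v) <- df[[1L]]
  labels <- NULL
  if (!is.null(labels_path)) {
    lab <- utils::read.delim(labels_path, stringsAsFactors = FALSE)
    labels <- stats::setNames(lab[[2L]], lab[[1L]])
  }
  domain_matrix(v, normalization = normalization, labels = labels)
}

#' Group labels of a domain matrix
#' @param m A `domain_matrix`.
#' @return Named character vector of `"HL"`/`"LL"` labels, or `NULL`.
#' @export
matrix_labels <- function(m) attr(m, "labels")
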