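#' Parse a HMMER3 per-domain table (domtblout)
#'
#' Reads the whitespace-delimited `--domtblout` format written by
#' `hmmsearch`/`hmmscan`: one row per domain match, `#` comment lines, and a
#' ragged free-text description in the trailing columns. For `hmmsearch`
#' against a proteome the *target* is the protein (ORF) and the *query* is
#' the profile HMM, which is the convention assumed here.
#'
#' @param con A file path or connection to a domtblout file, or a character
#'   vector of already-read lines.
#' @param genome_id Genome identifier attached to every hit. Defaults to the
#'   file name stem when `con` is a path, otherwise `"unknown"`.
#' @return A data frame of domain hits with columns `genome_id`, `orf_id`,
#'   `model_acc`, `model_name`, `full_seq_evalue`, `full_seq_bitscore`,
#'   `domain_bitscore`, `env_start`, `env_end`, `description`. An input with
#'   no data rows yields a zero-row frame.
#' @examples
#' lines <- c("# comment only")
#' nrow(parse_domtblout(lines))
#' @export
parse_domtblout <- function(con, genome_id = NULL) {
  if (is.character(con) && length(con) == 1L && file.exists(con)) {
    if (is.null(genome_id)) {
      genome_id <- sub("\\.[^.]*$", "", basename(con))
    }
    lines <- readLines(con, warn = FALSE)
  } else if (is.character(con)) {
    lines <- con
  } else {
    lines <- readLines(con, warn = FALSE)
  }
  if (is.null(genome_id)) genome_id <- "unknown"

  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0L) {
    return(empty_hits())
  }

  parse_row <- function(i) {
    f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(f) < 23L) {
      stop("malformed domtblout row at line ", i, ": expected >= 23 fields, got ",
           length(f), call. = FALSE)
    }
    num <- suppressWarnings(as.numeric(f[c(7L, 8L, 14L, 20L, 21L)]))
    if (anyNA(num)) {
      stop("malformed domtblout row at line ", i,
           ": non-numeric score/E-value field", call. = FALSE)
    }
    list(orf_id = f[1L], model_name = f[4L], model_acc = f[5L],
         full_seq_evalue = num[1L], full_seq_bitscore = num[2L],
         domain_bitscore = num[3L], env_start = as.integer(num[4L]),
         env_end = as.integer(num[5L]),
         description = paste(f[-seq_len(22L)], collapse = " "))
  }
  rows <- lapply(idx, parse_row)
  hits <- data.frame(
    genome_id = genome_id,
    orf_id = vapply(rows, `[[`, "", "orf_id"),
    model_acc = vapply(rows, `[[`, "", "model_acc"),
    model_name = vapply(rows, `[[`, "", "model_name"),
    full_seq_evalue = vapply(rows, `[[`, 0, "full_seq_evalue"),
    full_seq_bitscore = vapply(rows, `[[`, 0, "full_seq_bitscore"),
    domain_bitscore = vapply(rows, `[[`, 0, "domain_bitscore"),
    env_start = vapply(rows, `[[`, 0L, "env_start"),
    env_end = vapply(rows, `[[`, 0L, "env_end"),
    description = vapply(rows, `[[`, "", "description"),
    stringsAsFactors = FALSE
  )
  hits
}

empty_hits <- function() {
  data.frame(genome_id = character(), orf_id = character(),
             model_acc = character(), model_name = character(),
             full_seq_evalue = numeric(), full_seq_bitscore = numeric(),
             domain_bitscore = numeric(), env_start = integer(),
             env_end = integer(), description = character(),
             stringsAsFactors = FALSE)
}

#' Parse a directory (or manifest) of domtblout files
#'
#' @param paths Character vector of domtblout file paths.
#' @param genome_ids Optional genome ids, one per path; default file stems.
#' @return A single hit data frame (rbind of per-file parses). Duplicate
#'   genome ids across files are merged with a warning.
#' @export
parse_domtblout_set <- function(paths, genome_ids = NULL) {
  if (is.null(genome_ids)) {
    genome_ids <- sub("\\.[^.]*$", "", basename(paths))
  }
  stopifnot(length(genome_ids) == length(paths))
  if (anyDuplicated(genome_ids)) {
    warning("duplicate genome ids across files; hits are merged")
  }
  do.call(rbind, Map(parse_domtblout, paths, genome_ids))
}

#' Filter domain hits by full-sequence E-value
#'
#' Keeps hits with `full_seq_evalue <= e_max`, preserving order. The default
#' threshold 1e-9 is the strict cutoff used to call both Pfam and VFam
#' domains in predicted proteomes.
#'
#' @param hits Hit data frame as returned by [parse_domtblout()].
#' @param e_max Positive E-value ceiling (default `1e-9`).
#' @return The filtered hit data frame.
#' @export
filter_hits <- function(hits, e_max = 1e-9) {
  stopifnot(is.numeric(e_max), length(e_max) == 1L, e_max > 0)
  hits[hits$full_seq_evalue <= e_max, , drop = FALSE]
}

#' Deduplicate identical hit rows
#'
#' Drops exact duplicates on genome + ORF + model + envelope coordinates, the
#' granularity at which a domain match is unique.
#'
#' @param hits Hit data frame.
#' @return Deduplicated hit data frame.
#' @export
dedup_hits <- function(hits) {
  key <- paste(hits$genome_id, hits$orf_id, hits$model_acc,
               hits$env_start, hits$env_end, sep = "\r")
  hits[!duplicated(key), , drop = FALSE]
}
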