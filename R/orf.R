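# Gateway attL recombination-site constants flanking every synthesized ORF
ATTL1 <- "caaataatgattttattttgactgatagtgacctgttcgttgcaacacattgatgagcaatgcttttttataatgccaactttgtacaaaaaagcaggctac"
ATTL2 <- "ttggacccagctttcttgtacaaagttggcattataagaaagcattgcttatcaatttgttgcaacgaacaggtcactatcagtcaaaataaaatcattatttg"

# universal primers sitting in the vector backbone, outside the attL sites
UNI9_FOR <- "GAAGTGCCATTCCGCCTGACCT"
UNI9_REV <- "CACTGAGCCTCCACCTAGCCT"

#' Gateway attL1/attL2 site sequences
#' @return Named character vector with elements `attL1` and `attL2`
#'   (lowercase, as used in construct assembly).
#' @export
attl_sequences <- function() c(attL1 = ATTL1, attL2 = ATTL2)

#' Uni9 universal primer pair
#' @return Named character vector with elements `forward` and `reverse`.
#' @export
uni9_primers <- function() c(forward = UNI9_FOR, reverse = UNI9_REV)

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Remove the terminal stop codon from a cDNA
#'
#' Treats the input as a frame-0 CDS. If the final in-frame codon is a stop
#' (TAA/TAG/TGA, case-insensitive) it is removed; otherwise the sequence is
#' returned unchanged with a warning recorded. Input case is preserved.
#' Internal in-frame stops and out-of-frame lengths are warned about but
#' never edited.
#'
#' @param cdna DNA string over A/C/G/T/N, any case, length >= 3.
#' @return List with `insert`, `stop_removed` (logical), `warnings`
#'   (character vector of issues found).
#' @export
strip_stop <- function(cdna) {
  stopifnot(is.character(cdna), length(cdna) == 1L)
  if (grepl("[^ACGTNacgtn]", cdna)) {
    stop("sequence contains characters outside A/C/G/T/N", call. = FALSE)
  }
  len <- nchar(cdna)
  if (len < 3L) stop("sequence shorter than one codon", call. = FALSE)
  warnings <- character()
  if (len %% 3L != 0L) {
    return(list(insert = cdna, stop_removed = FALSE,
                warnings = "length not a multiple of 3; no stop removed"))
  }
  codons <- toupper(substring(cdna, seq(1L, len - 2L, by = 3L),
                              seq(3L, len, by = 3L)))
  n_codons <- length(codons)
  if (n_codons > 2L && any(codons[-c(1L, n_codons)] %in% STOP_CODONS)) {
    warnings <- c(warnings, "internal in-frame stop codon present")
  }
  if (codons[n_codons] %in% STOP_CODONS) {
    list(insert = substr(cdna, 1L, len - 3L), stop_removed = TRUE,
         warnings = warnings)
  } else {
    list(insert = cdna, stop_removed = FALSE,
         warnings = c(warnings, "no terminal stop codon found"))
  }
}

#' Flank an insert with the Gateway attL sites
#'
#' @param insert Non-empty DNA string (typically a stop-stripped CDS; case
#'   preserved).
#' @param orf_id Identifier carried into the construct record.
#' @param stop_removed,warnings Provenance carried from [strip_stop()].
#' @return An `orf_construct`: list with `orf_id`, `insert`, `construct`
#'   (`attL1 + insert + attL2`), `stop_removed`, `warnings`.
#' @export
flank_attl <- function(insert, orf_id = "orf", stop_removed = NA, warnings = character()) {
  stopifnot(is.character(insert), length(insert) == 1L)
  if (nchar(insert) == 0L) stop("empty insert", call. = FALSE)
  structure(list(orf_id = orf_id, insert = insert,
                 construct = paste0(ATTL1, insert, ATTL2),
                 stop_removed = stop_removed, warnings = warnings),
            class = "orf_construct")
}

#' @export
print.orf_construct <- function(x, ...) {
  cat(sprintf("orf_construct %s: insert %d bp, construct %d bp, stop_removed=%s\n",
              x$orf_id, nchar(x$insert), nchar(x$construct), x$stop_removed))
  invisible(x)
}

#' Exact primer matches on both strands
#'
#' Finds every exact, case-insensitive occurrence of the primer on the
#' forward strand and of its reverse complement (a match of the primer on
#' the reverse strand), reporting forward-strand start positions.
#'
#' @param construct DNA string to search.
#' @param primer Primer sequence, length >= 10.
#' @return Data frame with `position` (1-based forward-strand start) and
#'   `strand` (`"+"`/`"-"`); zero rows when absent.
#' @export
find_primer <- function(construct, primer) {
  stopifnot(nchar(primer) >= 10L)
  subj <- Biostrings::DNAString(toupper(construct))
  fwd <- Biostrings::matchPattern(Biostrings::DNAString(toupper(primer)), subj)
  rev <- Biostrings::matchPattern(
    Biostrings::reverseComplement(Biostrings::DNAString(toupper(primer))), subj)
  out <- data.frame(
    position = c(Biostrings::start(fwd), Biostrings::start(rev)),
    strand = c(rep("+", length(fwd)), rep("-", length(rev))),
    stringsAsFactors = FALSE)
  out[order(out$position, out$strand), , drop = FALSE]
}

#' Length statistics of a sequence set
#'
#' @param sequences A [Biostrings::DNAStringSet] or character vector of
#'   sequences (>= 1).
#' @param thresholds Numeric thresholds (bp); for each, the fraction of
#'   sequences strictly shorter is reported.
#' @return List with `n`, `mean_bp`, and `fraction_below` (named by
#'   threshold).
#' @export
length_stats <- function(sequences, thresholds = 1500) {
  lens <- if (inherits(sequences, "XStringSet")) {
    Biostrings::width(sequences)
  } else {
    nchar(sequences)
  }
  if (length(lens) == 0L) stop("empty sequence set", call. = FALSE)
  list(n = length(lens), mean_bp = mean(lens),
       fraction_below = stats::setNames(
         vapply(thresholds, function(th) mean(lens < th), numeric(1L)),
         thresholds))
}

#' GC content of a sequence set
#'
#' @param sequences A [Biostrings::DNAStringSet] or character vector.
#' @return Overall G+C percentage across all sequences.
#' @export
gc_content <- function(sequences) {
  if (!inherits(sequences, "XStringSet")) {
    sequences <- Biostrings::DNAStringSet(toupper(sequences))
  }
  fr <- Biostrings::letterFrequency(sequences, c("G", "C", "A", "T"))
  100 * sum(fr[, c("G", "C")]) / sum(fr)
}

#' Row-major plate-map assignment
#'
#' @param n Number of constructs.
#' @param plate_size 96 or 384 wells.
#' @return Data frame with `plate`, `well` (e.g. `"A01"`), in input order.
#' @export
plate_map <- function(n, plate_size = 96L) {
  stopifnot(plate_size %in% c(96L, 384L))
  ncol_ <- if (plate_size == 96L) 12L else 24L
  nrow_ <- plate_size / ncol_
  idx <- seq_len(n) - 1L
  data.frame(
    plate = idx %/% plate_size + 1L,
    well = sprintf("%s%02d", LETTERS[(idx %% plate_size) %/% ncol_ + 1L],
                   (idx %% ncol_) + 1L),
    stringsAsFactors = FALSE)
}

#' Design Gateway-ready constructs for a cDNA set
#'
#' Full ORFeome design step: strips terminal stops, flanks each insert with
#' the attL1/attL2 sites, assigns plate positions in input order, and
#' summarizes lengths.
#'
#' @param cdnas Named [Biostrings::DNAStringSet] or named character vector
#'   of frame-0 cDNA sequences.
#' @param plate_size Plate format for the map (96 or 384).
#' @return List with `constructs` (named character vector of attL-flanked
#'   sequences), `report` (data frame: `orf_id`, `insert_bp`,
#'   `construct_bp`, `stop_removed`, `warnings`, `plate`, `well`), and
#'   `stats` ([length_stats()] of the inserts).
#' @export
orf_design <- function(cdnas, plate_size = 96L) {
  seqs <- if (inherits(cdnas, "XStringSet")) {
    stats::setNames(as.character(cdnas), names(cdnas))
  } else {
    cdnas
  }
  stopifnot(length(seqs) >= 1L)
  if (is.null(names(seqs))) names(seqs) <- paste0("orf", seq_along(seqs))
  designs <- lapply(names(seqs), function(id) {
    st <- strip_stop(seqs[[id]])
    flank_attl(st$insert, orf_id = id, stop_removed = st$stop_removed,
               warnings = st$warnings)
  })
  pm <- plate_map(length(designs), plate_size)
  report <- data.frame(
    orf_id = vapply(designs, `[[`, "", "orf_id"),
    insert_bp = vapply(designs, function(d) nchar(d$insert), integer(1L)),
    construct_bp = vapply(designs, function(d) nchar(d$construct), integer(1L)),
    stop_removed = vapply(designs, `[[`, NA, "stop_removed"),
    warnings = vapply(designs, function(d) paste(d$warnings, collapse = "; "), ""),
    plate = pm$plate, well = pm$well,
    stringsAsFactors = FALSE)
  constructs <- stats::setNames(
    vapply(designs, `[[`, "", "construct"),
    report$orf_id)
  list(constructs = constructs, report = report,
       stats = length_stats(vapply(designs, `[[`, "", "insert")))
}
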