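#' Simulation scenario for the synthetic pipeline inputs
#'
#' Defines the study conditions emulated by every generator: 25 high-light
#' vs 15 low-light genomes, 200 domain families of which 20 carry planted
#' group fold-changes in the 2-10x range on a log-normal noise background.
#' Four of the planted families carry the effect sizes reported for the
#' real ecotype panel: PF00288 (GHMP kinase, ~5x LL-higher), PF02421
#' (ferrous iron transporter B, ~2x LL-higher), PF16881 (lipoyl synthase
#' N-terminal, ~10x HL-higher), PF06182 (ABC-2 transporter, ~3x HL-higher).
#' The VFam overlay plants a low-light excess of 12 co-domain hits per
#' genome over a high-light mean of 10.8, so the panel-wide mean is 15.3
#' VFams/genome on discriminant-Pfam ORFs.
#'
#' @param n_hl,n_ll Genomes per group.
#' @param n_features Total domain families.
#' @param planted Data frame with columns `model_acc`, `group`
#'   (`"HL"`/`"LL"`: which group is elevated), `fold` (>= 1). Default: the
#'   four reported effects plus 16 synthetic families with folds spread over
#'   2-10, alternating groups.
#' @param noise_sdlog Log-scale noise SD of the bit-score background.
#' @param baseline_meanlog Log-scale baseline of bit-score sums.
#' @param vfam_delta Planted LL - HL difference in co-domain VFam hits.
#' @param vfam_hl_mean High-light mean co-domain VFam hits per genome.
#' @param vfam_background Mean VFam hits per genome on non-discriminant ORFs.
#' @param seed Integer seed used by the generators.
#' @return A `sim_scenario` list.
#' @export
simulation_scenario <- function(n_hl = 25L, n_ll = 15L, n_features = 200L,
                                planted = default_planted(),
                                noise_sdlog = 0.5, baseline_meanlog = log(50),
                                vfam_delta = 12, vfam_hl_mean = 10.8,
                                vfam_background = 5, seed = 1L) {
  stopifnot(n_hl >= 2L, n_ll >= 2L, n_features >= nrow(planted),
            noise_sdlog > 0, all(planted$fold >= 1),
            all(planted$group %in% c("HL", "LL")),
            !anyDuplicated(planted$model_acc))
  structure(list(n_hl = as.integer(n_hl), n_ll = as.integer(n_ll),
                 n_features = as.integer(n_features), planted = planted,
                 noise_sdlog = noise_sdlog, baseline_meanlog = baseline_meanlog,
                 vfam_delta = vfam_delta, vfam_hl_mean = vfam_hl_mean,
                 vfam_background = vfam_background, seed = seed),
            class = "sim_scenario")
}

#' @rdname simulation_scenario
#' @export
default_planted <- function() {
  named <- data.frame(
    model_acc = c("PF00288", "PF02421", "PF16881", "PF06182"),
    group = c("LL", "LL", "HL", "HL"),
    fold = c(5, 2, 10, 3),
    stringsAsFactors = FALSE)
  extra <- data.frame(
    model_acc = sprintf("PF8%04d", seq_len(16L)),
    group = rep(c("HL", "LL"), 8L),
    fold = rep(c(2, 4, 6, 8, 10, 3, 5, 7), 2L),
    stringsAsFactors = FALSE)
  rbind(named, extra)
}

#' Generate a labeled genomes x domains bit-score matrix
#'
#' Each cell is log-normal: `meanlog = baseline + log(fold)` when the
#' family is planted for that genome's group, `baseline` otherwise, with
#' common `sdlog` noise. Values are rounded to 0.1 (the precision at which
#' bit scores are printed). Deterministic per scenario seed.
#'
#' @param scenario A [simulation_scenario()].
#' @return List with `matrix` (a raw-sum `domain_matrix` with labels) and
#'   `truth` (the planted table).
#' @export
generate_matrix <- function(scenario) {
  stopifnot(inherits(scenario, "sim_scenario"))
  genome_ids <- c(sprintf("HL%02d", seq_len(scenario$n_hl)),
                  sprintf("LL%02d", seq_len(scenario$n_ll)))
  labels <- stats::setNames(rep(c("HL", "LL"), c(scenario$n_hl, scenario$n_ll)),
                            genome_ids)
  n_null <- scenario$n_features - nrow(scenario$planted)
  model_accs <- c(scenario$planted$model_acc,
                  sprintf("PF7%04d", seq_len(n_null)))
  shift <- matrix(0, length(genome_ids), length(model_accs),
                  dimnames = list(genome_ids, model_accs))
  for (i in seq_len(nrow(scenario$planted))) {
    pl <- scenario$planted[i, ]
    shift[labels == pl$group, pl$model_acc] <- log(pl$fold)
  }
  values <- with_seed(scenario$seed, {
    matrix(stats::rlnorm(length(shift),
                         meanlog = scenario$baseline_meanlog + as.vector(shift),
                         sdlog = scenario$noise_sdlog),
           nrow(shift), ncol(shift), dimnames = dimnames(shift))
  })
  values <- round(values, 1L)
  list(matrix = domain_matrix(values, normalization = "raw_sum", labels = labels),
       truth = scenario$planted)
}

# one domtblout-format row (23 columns, whitespace-aligned free layout)
format_domtbl_row <- function(orf_id, model_name, model_acc, evalue, score,
                              env_start, env_end, tlen = 300L) {
  sprintf(paste("%s - %d %s %s %d %.1e %.1f 0.0 1 1 %.1e %.1e %.1f 0.0",
                "1 %d %d %d %d %d 0.90 synthetic hit"),
          orf_id, tlen, model_name, model_acc, 200L, evalue, score,
          evalue, evalue, score, env_end - env_start + 1L,
          env_start, env_end, env_start, env_end)
}

#' Decompose a bit-score matrix into synthetic domtblout hits
#'
#' Splits every nonzero cell into one or more hit rows whose bit scores sum
#' exactly (at 0.1 precision) to the cell value, assigns sequential ORF
#' ids, draws E-values far below the 1e-9 call threshold, and (optionally)
#' writes one valid domtblout file per genome that [parse_domtblout()]
#' reads back verbatim.
#'
#' @param m A raw-sum `domain_matrix`.
#' @param dir Output directory for per-genome `<genome>.domtbl` files, or
#'   `NULL` to skip writing.
#' @param hits_lambda Poisson rate for extra hits per cell (cell hit count
#'   is `1 + rpois(hits_lambda)`).
#' @param seed Integer seed.
#' @return List with `hits` (hit data frame in the [parse_domtblout()]
#'   layout), `catalog` (genome_id, orf_id, model_acc per hit), and `paths`
#'   (named by genome, `NULL` if not written).
#' @export
generate_domtblout <- function(m, dir = NULL, hits_lambda = 0.5, seed = 1L) {
  stopifnot(inherits(m, "domain_matrix"),
            attr(m, "normalization") == "raw_sum")
  hits <- with_seed(seed, {
    rows <- vector("list", nrow(m) * ncol(m))
    ri <- 0L
    for (g in rownames(m)) {
      orf_counter <- 0L
      for (acc in colnames(m)) {
        tenths <- round(m[g, acc] * 10)
        if (tenths <= 0) next
        k <- min(1L + stats::rpois(1L, hits_lambda), tenths)
        # k positive tenth-integer parts summing exactly to the cell value
        parts <- rep(tenths %/% k, k)
        extra <- tenths - sum(parts)
        if (extra > 0) parts[seq_len(extra)] <- parts[seq_len(extra)] + 1L
        for (s in parts) {
          orf_counter <- orf_counter + 1L
          ri <- ri + 1L
          ev <- 10^(-stats::runif(1L, 10, 30))
          st <- sample.int(200L, 1L)
          rows[[ri]] <- data.frame(
            genome_id = g, orf_id = sprintf("orf_%s_%04d", g, orf_counter),
            model_acc = acc, model_name = acc,
            full_seq_evalue = ev, full_seq_bitscore = s / 10,
            domain_bitscore = s / 10,
            env_start = st, env_end = st + 80L,
            description = "synthetic hit", stringsAsFactors = FALSE)
        }
      }
    }
    do.call(rbind, rows[seq_len(ri)])
  })
  paths <- NULL
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- stats::setNames(file.path(dir, paste0(rownames(m), ".domtbl")),
                             rownames(m))
    for (g in rownames(m)) {
      h <- hits[hits$genome_id == g, , drop = FALSE]
      lines <- c("# synthetic hmmsearch domtblout",
                 mapply(format_domtbl_row, h$orf_id, h$model_name, h$model_acc,
                        h$full_seq_evalue, h$full_seq_bitscore,
                        h$env_start, h$env_end))
      writeLines(lines, paths[[g]])
    }
  }
  list(hits = hits,
       catalog = hits[, c("genome_id", "orf_id", "model_acc")],
       paths = paths)
}

#' Overlay endogenous viral-element (VFam) hits with a planted group effect
#'
#' Per genome, draws a Poisson number of VFam hits placed on ORFs that
#' carry a discriminant (ANN-set) Pfam — mean `vfam_hl_mean` for HL genomes
#' and `vfam_hl_mean + vfam_delta` for LL genomes — plus Poisson background
#' VFam hits on ORFs outside the discriminant set. Each hit gets distinct
#' envelope coordinates so deduplication keeps them apart.
#'
#' @param catalog Hit catalog from [generate_domtblout()].
#' @param ann_pfams Discriminant Pfam accessions to co-locate with.
#' @param labels Named `"HL"`/`"LL"` vector over genome ids.
#' @param vfam_delta Planted LL - HL mean difference in co-domain hits.
#' @param vfam_hl_mean HL-group mean co-domain hits per genome (the implied
#'   LL mean must stay non-negative).
#' @param background Mean background VFam hits per genome.
#' @param dir Optional output directory for `<genome>.vfam.domtbl` files.
#' @param seed Integer seed.
#' @return List with `hits` (VFam hit data frame), `truth` (per-genome
#'   realized co-domain hit counts), and `paths`.
#' @export
generate_vfam_overlay <- function(catalog, ann_pfams, labels, vfam_delta = 12,
                                  vfam_hl_mean = 10.8, background = 5,
                                  dir = NULL, seed = 1L) {
  stopifnot(length(ann_pfams) > 0L)
  means <- c(HL = vfam_hl_mean, LL = vfam_hl_mean + vfam_delta)
  if (any(means < 0)) stop("implied Poisson mean is negative", call. = FALSE)
  genomes <- unique(catalog$genome_id)
  stopifnot(all(genomes %in% names(labels)))
  vfam_pool <- sprintf("VFAM%04d", seq_len(30L))

  out <- with_seed(seed, {
    rows <- list()
    truth <- data.frame(genome_id = genomes,
                        label = labels[genomes],
                        n_codomain_hits = 0L, stringsAsFactors = FALSE)
    for (gi in seq_along(genomes)) {
      g <- genomes[gi]
      ann_orfs <- unique(catalog$orf_id[catalog$genome_id == g &
                                          catalog$model_acc %in% ann_pfams])
      m_g <- stats::rpois(1L, means[[labels[[g]]]])
      m_g <- min(m_g, length(ann_orfs) * 50L)
      b_g <- stats::rpois(1L, background)
      orfs <- c(if (m_g > 0) sample(ann_orfs, m_g, replace = TRUE),
                if (b_g > 0) sprintf("vorf_%s_%03d", g, seq_len(b_g)))
      n <- m_g + b_g
      if (n > 0) {
        st <- 10L * seq_len(n) + 1L   # distinct coords: no dedup collisions
        rows[[g]] <- data.frame(
          genome_id = g, orf_id = orfs,
          model_acc = sample(vfam_pool, n, replace = TRUE),
          model_name = "synthetic_vfam",
          full_seq_evalue = 10^(-stats::runif(n, 10, 30)),
          full_seq_bitscore = round(stats::rlnorm(n, log(40), 0.3), 1L),
          domain_bitscore = 0, env_start = st, env_end = st + 8L,
          description = "synthetic vfam hit", stringsAsFactors = FALSE)
      }
      truth$n_codomain_hits[gi] <- m_g
    }
    list(hits = do.call(rbind, rows), truth = truth)
  })
  hits <- out$hits
  hits$domain_bitscore <- hits$full_seq_bitscore
  rownames(hits) <- NULL
  paths <- NULL
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- stats::setNames(file.path(dir, paste0(genomes, ".vfam.domtbl")),
                             genomes)
    for (g in genomes) {
      h <- hits[hits$genome_id == g, , drop = FALSE]
      writeLines(c("# synthetic vfam domtblout",
                   if (nrow(h) > 0)
                     mapply(format_domtbl_row, h$orf_id, h$model_name,
                            h$model_acc, h$full_seq_evalue,
                            h$full_seq_bitscore, h$env_start, h$env_end)),
                 paths[[g]])
    }
  }
  list(hits = hits, truth = out$truth, paths = paths)
}

SENSE_CODONS <- {
  bases <- c("T", "C", "A", "G")
  all64 <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  setdiff(all64, c("TAA", "TAG", "TGA"))
}

#' Generate toy in-frame cDNA sequences
#'
#' Random coding sequences — ATG start, random sense codons, one terminal
#' stop — with total lengths drawn from a log-normal matched to `mean_bp`
#' and rounded to multiples of 3. The default `sdlog = 0.6` puts about 92%
#' of sequences under 1.5 kb at the default mean, matching the length
#' profile of the compact cyanobacterial ORFeomes this emulates.
#'
#' @param n Number of sequences (>= 1).
#' @param mean_bp Target mean length in bp.
#' @param sdlog Log-scale SD of the length law.
#' @param seed Integer seed.
#' @return A named [Biostrings::DNAStringSet].
#' @export
generate_cdna <- function(n, mean_bp = 767, sdlog = 0.6, seed = 1L) {
  stopifnot(n >= 1L, mean_bp >= 30)
  with_seed(seed, {
    lens <- stats::rlnorm(n, meanlog = log(mean_bp) - sdlog^2 / 2, sdlog = sdlog)
    lens <- pmax(9L, 3L * round(lens / 3))
    seqs <- vapply(lens, function(L) {
      n_mid <- L / 3 - 2L
      paste0("ATG",
             paste(sample(SENSE_CODONS, n_mid, replace = TRUE), collapse = ""),
             sample(c("TAA", "TAG", "TGA"), 1L))
    }, character(1L))
    Biostrings::DNAStringSet(stats::setNames(seqs, sprintf("cdna_%04d", seq_len(n))))
  })
}
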