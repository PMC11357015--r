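test_that("correlation_distance matches hand Pearson values", {
  expect_equal(correlation_distance(1:5, 1:5), 0)
  expect_equal(correlation_distance(1:5, 5:1), 2)
  expect_equal(correlation_distance(c(1, 2, 3), c(1, 3, 2)), 0.5)
  expect_warning(d <- correlation_distance(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_equal(d, 1)
  expect_equal(correlation_distance(c(1, 5, 2), c(9, 0, 4)),
               correlation_distance(c(9, 0, 4), c(1, 5, 2)))
})

test_that("hierarchical clustering merges the closest structure first", {
  v <- rbind(g1 = c(1, 2, 3, 4), g2 = c(1, 2, 3, 4),
             g3 = c(9, 1, 0, 2), g4 = c(0, 8, 7, 1))
  colnames(v) <- paste0("PF", 1:4)
  m <- domain_matrix(v, "raw_sum")
  cl <- hierarchical_cluster(m, "genomes", "euclidean")
  expect_equal(sort(cl$order), 1:4)
  expect_equal(min(cl$height), 0)           # duplicated rows merge at height 0
  expect_equal(sort(cl$merge[1, ]), c(-2, -1))
  expect_true(all(diff(cl$height) >= -1e-12))

  # 1-D set {0, 1, 10}: {0, 1} must merge first under euclidean distance
  v2 <- cbind(PF1 = c(0, 1, 10), PF2 = c(0, 0, 0))
  rownames(v2) <- paste0("g", 1:3)
  cl2 <- hierarchical_cluster(domain_matrix(v2, "raw_sum"), "genomes", "euclidean")
  expect_equal(sort(cl2$merge[1, ]), c(-2, -1))

  # two well-separated planted blocks: first merges are within-block
  set.seed(5)
  blocks <- rbind(matrix(rnorm(8, 0), 2), matrix(rnorm(8, 50), 2))
  dimnames(blocks) <- list(paste0("g", 1:4), paste0("PF", 1:4))
  cl3 <- hierarchical_cluster(domain_matrix(blocks, "raw_sum"), "genomes", "euclidean")
  expect_true(all(abs(cl3$merge[1, ]) %in% 1:2) || all(abs(cl3$merge[1, ]) %in% 3:4))

  expect_error(hierarchical_cluster(
    domain_matrix(v[1, , drop = FALSE], "raw_sum"), "genomes"), "two items")
})

test_that("clustering is invariant to row shuffling up to relabeling", {
  sc <- simulation_scenario(n_hl = 5, n_ll = 5, n_features = 30,
                            planted = default_planted()[1:4, ], seed = 8)
  m <- generate_matrix(sc)$matrix
  cl <- hierarchical_cluster(m, "genomes", "pearson")
  set.seed(9)
  perm <- sample(nrow(m))
  m2 <- domain_matrix(unclass(m)[perm, ], "raw_sum")
  cl2 <- hierarchical_cluster(m2, "genomes", "pearson")
  expect_equal(sort(cl$height), sort(cl2$height))
  for (k in 2:4) {
    p1 <- cutree(cl$hclust, k)
    p2 <- cutree(cl2$hclust, k)[match(rownames(m), rownames(m2)[seq_len(nrow(m))])]
    p2 <- cutree(cl2$hclust, k)[rownames(m)]
    # same partition up to cluster relabeling
    expect_equal(length(unique(paste(p1, p2))), k)
  }
})

test_that("bicluster orders both axes of the matrix", {
  sc <- simulation_scenario(n_hl = 4, n_ll = 4, n_features = 12,
                            planted = default_planted()[1:3, ], seed = 10)
  m <- generate_matrix(sc)$matrix
  bc <- bicluster(m, "euclidean")
  expect_equal(dim(bc$ordered), dim(m))
  expect_setequal(rownames(bc$ordered), rownames(m))
  expect_setequal(colnames(bc$ordered), colnames(m))
})

test_that("PLS ordination separates labeled groups and loads informative features", {
  sc <- simulation_scenario(seed = 13)
  m <- normalize_matrix(generate_matrix(sc)$matrix)
  pl <- pls_ordination(m)
  expect_equal(ncol(pl$scores), 2L)
  expect_equal(unname(colMeans(pl$scores)), c(0, 0), tolerance = 1e-8)
  expect_true(all(pl$explained >= 0 & pl$explained <= 1))
  grp <- tapply(pl$scores[, 1], matrix_labels(m), mean)
  expect_true(sign(grp["HL"]) != sign(grp["LL"]))

  # single informative feature dominates the component-1 loading
  set.seed(14)
  v <- matrix(rnorm(20 * 10), 20, 10,
              dimnames = list(paste0("g", 1:20), paste0("PF", 1:10)))
  lab <- setNames(rep(c("HL", "LL"), each = 10), rownames(v))
  v[, 1] <- ifelse(lab == "HL", 10, -10) + rnorm(20, sd = 0.1)
  pl2 <- pls_ordination(domain_matrix(v, "none", labels = lab))
  expect_equal(which.max(abs(pl2$loadings[, 1])), c(PF1 = 1L))

  # shuffled labels collapse the separation statistic
  sep_stat <- function(scores, labels) {
    s <- scores[, 1]
    gm <- tapply(s, labels, mean)
    diff_sq <- (gm[1] - gm[2])^2
    diff_sq / stats::var(s)
  }
  obs <- sep_stat(pl$scores, matrix_labels(m))
  set.seed(15)
  worse <- replicate(100, {
    shuffled <- setNames(sample(matrix_labels(m)), rownames(m))
    ms <- domain_matrix(unclass(m), "per_genome_rate", labels = shuffled)
    sep_stat(pls_ordination(ms)$scores, shuffled) < obs
  })
  expect_gte(mean(worse), 0.95)
})

test_that("PLS finds no separation after the label signal is regressed out", {
  sc <- simulation_scenario(n_hl = 10, n_ll = 10, n_features = 40,
                            planted = default_planted()[1:4, ], seed = 16)
  m <- generate_matrix(sc)$matrix
  lab <- matrix_labels(m)
  y <- ifelse(lab == "HL", 1, -1)
  v <- apply(unclass(m), 2, function(col) stats::resid(stats::lm(col ~ y)))
  rownames(v) <- rownames(m)
  mo <- domain_matrix(v, "none", labels = lab)
  plo <- pls_ordination(mo)
  gm <- tapply(plo$scores[, 1], lab, mean)
  # between-group difference is numerically zero after orthogonalization
  expect_equal(unname(gm["HL"] - gm["LL"]), 0, tolerance = 1e-6)
})

test_that("constant feature columns are dropped with a warning", {
  v <- cbind(PF1 = c(1, 2, 3, 4), PF2 = rep(7, 4), PF3 = c(4, 3, 2, 1))
  rownames(v) <- paste0("g", 1:4)
  m <- domain_matrix(v, "none",
                     labels = setNames(rep(c("HL", "LL"), 2), rownames(v)))
  expect_warning(pl <- pls_ordination(m), "constant")
  expect_equal(nrow(pl$loadings), 2L)
})
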