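test_that("robust_sigma matches the normal-IQR construction", {
  expect_equal(robust_sigma(rep(3, 10)), 0)
  expect_error(robust_sigma(1), "n >= 2")
  # type-7 quartiles of this vector are exactly the N(0,1) quartiles
  q <- c(-0.67449, -0.67449, 0.67449, 0.67449)
  expect_equal(robust_sigma(q), (2 * 0.67449) / 1.3489795, tolerance = 1e-12)
  expect_equal(robust_sigma(q), 1.0, tolerance = 1e-4)
  set.seed(42)
  expect_equal(robust_sigma(rnorm(1e6)), 1.0, tolerance = 0.01)
})

test_that("practical difference threshold is 6 * proportion * sigma", {
  expect_equal(practical_difference_threshold(0), 0)
  expect_equal(practical_difference_threshold(1), 0.6)
  expect_equal(practical_difference_threshold(2, 0.25), 3.0)
  expect_error(practical_difference_threshold(-1), "non-negative")
})

test_that("huber_estimate downweights outliers and agrees with MASS on clean data", {
  fit <- huber_estimate(c(1, 2, 3))
  expect_equal(fit$location, 2)
  expect_equal(fit$weights, rep(1, 3))

  fit <- huber_estimate(c(1, 2, 3, 100))
  expect_lt(abs(fit$location - 2), abs(mean(c(1, 2, 3, 100)) - 2))
  expect_lt(fit$weights[4], min(fit$weights[1:3]))
  expect_true(all(fit$weights > 0 & fit$weights <= 1))
  expect_gte(fit$location, 1); expect_lte(fit$location, 100)

  expect_equal(huber_estimate(rep(5, 4))$location, 5)

  # MASS::huber uses the MAD scale; locations agree closely on well-behaved data
  set.seed(7)
  x <- c(rnorm(50), 25)
  expect_equal(huber_estimate(x)$location, MASS::huber(x, k = 1.345)$mu,
               tolerance = 1e-4)
})

test_that("TOST equivalence p is the max one-sided p and behaves at the limits", {
  set.seed(1)
  a <- rnorm(60); b <- a
  expect_lt(tost_equivalence(a, b, delta = 1), 1e-6)

  b2 <- a + 10
  expect_gt(tost_equivalence(a, b2, delta = 1), 0.99)

  for (i in 1:20) {
    x <- rnorm(10); y <- rnorm(8, sd = 1.5)
    d <- runif(1, 0, 2)
    expect_equal(tost_equivalence(x, y, d), tost_oracle(x, y, d), tolerance = 1e-10)
    expect_gte(tost_equivalence(x, y, 0), 0.5)
  }

  # fixed data: evidence for equivalence never decreases as the margin grows
  x <- rnorm(12); y <- rnorm(12)
  ps <- vapply(seq(0, 3, by = 0.25), function(d) tost_equivalence(x, y, d),
               numeric(1L))
  expect_true(all(diff(ps) <= 1e-12))

  expect_equal(tost_equivalence(rep(1, 3), rep(1, 3), 0.5), 0)
  expect_equal(tost_equivalence(rep(1, 3), rep(1, 3), 0), 1)
})

test_that("screen_feature calls match simulation ground truth", {
  # equivalence detection needs groups large enough to resolve the 0.6*sigma
  # margin; identically drawn large groups are called equivalent
  set.seed(100)
  eq_calls <- replicate(200, {
    screen_feature(rlnorm(100, 4, 0.5), rlnorm(100, 4, 0.5))$call
  })
  expect_gte(mean(eq_calls == "practical_equivalence"), 0.9)

  set.seed(101)
  diff_calls <- replicate(50, {
    hl <- rnorm(25); ll <- rnorm(15) + 10 * sd(c(hl))
    screen_feature(hl, ll)$call
  })
  expect_true(all(diff_calls == "practical_difference"))

  # tiny noisy groups rarely support either verdict
  set.seed(102)
  tiny <- replicate(100, screen_feature(rnorm(2), rnorm(2))$call)
  expect_gt(mean(tiny == "inconclusive"), 0.5)

  r <- screen_feature(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$logworth, -log10(r$p_value))
  expect_equal(r$practical_difference, 0.6 * r$sigma_hat)
})

test_that("fdr_adjust equals p.adjust examples and the step-up oracle", {
  expect_equal(fdr_adjust(0.03), 0.03)
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(fdr_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_error(fdr_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_equal(fdr_adjust(numeric()), numeric())

  p <- c(0.01, 0.02, 0.04)
  expect_true(all(fdr_adjust(p) >= p))
})

test_that("response_screen ranks a planted feature first and handles edge shapes", {
  planted <- data.frame(model_acc = "PF00001", group = "LL", fold = 5)
  sc <- simulation_scenario(n_features = 200, planted = planted, seed = 21)
  m <- normalize_matrix(generate_matrix(sc)$matrix)
  scr <- response_screen(m)
  expect_s3_class(scr, "response_screen")
  expect_equal(top_features(scr, 1)$model_acc, "PF00001")
  expect_equal(scr$fdr_logworth, -log10(scr$fdr_p))
  expect_true(all(scr$fdr_p >= scr$p_value - 1e-12))
  expect_true(all(scr$call %in% c("practical_difference", "practical_equivalence",
                                  "inconclusive")))

  empty <- domain_matrix(matrix(numeric(), 4, 0,
                                dimnames = list(paste0("g", 1:4), NULL)),
                         "raw_sum",
                         labels = setNames(rep(c("HL", "LL"), 2), paste0("g", 1:4)))
  expect_equal(nrow(response_screen(empty)), 0L)

  no_labels <- domain_matrix(matrix(1:4, 2, 2,
                                    dimnames = list(c("a", "b"), c("x", "y"))))
  expect_error(response_screen(no_labels), "labels")
})

test_that("top_features breaks fdr ties deterministically", {
  v <- matrix(rep(c(1, 1, 5, 5), 3), 4, 3,
              dimnames = list(paste0("g", 1:4), c("PFB", "PFA", "PFC")))
  v[, 2] <- v[, 2] * 2  # larger |mean_diff| for PFA
  m <- domain_matrix(v, "raw_sum",
                     labels = setNames(c("HL", "HL", "LL", "LL"), paste0("g", 1:4)))
  scr <- response_screen(m)
  expect_equal(length(unique(scr$fdr_p)), 1L)
  expect_equal(top_features(scr)$model_acc[1], "PFA")
  expect_equal(top_features(scr)$model_acc[2:3], c("PFB", "PFC"))
})
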