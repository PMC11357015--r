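# run expr under a fixed RNG seed without disturbing the caller's stream
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Configuration for the boosted TanH network
#'
#' Defaults mirror the published classifier: four sequential (boosted)
#' models of three TanH hidden nodes each, learning rate 0.1, squared (L2)
#' penalty on the weights, z-transformed covariates, and a randomly selected
#' 20% stratified holdout.
#'
#' @param n_models Number of boosting stages.
#' @param hidden_nodes TanH nodes per stage.
#' @param learning_rate Shrinkage applied to each stage's contribution,
#'   in (0, 1].
#' @param penalty_lambda L2 penalty weight on stage parameters.
#' @param holdout_fraction Fraction of genomes held out per class, in (0, 1).
#' @param seed Integer seed controlling the holdout draw and weight
#'   initialization.
#' @param standardize Z-standardize covariates with training-set statistics.
#' @param max_iter Optimizer iteration cap per stage.
#' @return A validated `ann_config` list.
#' @export
ann_config <- function(n_models = 4L, hidden_nodes = 3L, learning_rate = 0.1,
                       penalty_lambda = 1e-3, holdout_fraction = 0.2,
                       seed = 1L, standardize = TRUE, max_iter = 500L) {
  stopifnot(n_models >= 1L, hidden_nodes >= 1L,
            learning_rate > 0, learning_rate <= 1,
            penalty_lambda >= 0,
            holdout_fraction > 0, holdout_fraction < 1)
  structure(list(n_models = as.integer(n_models),
                 hidden_nodes = as.integer(hidden_nodes),
                 activation = "tanh", learning_rate = learning_rate,
                 penalty = "squared", penalty_lambda = penalty_lambda,
                 holdout_fraction = holdout_fraction, seed = seed,
                 standardize = standardize, max_iter = as.integer(max_iter)),
            class = "ann_config")
}

#' Stratified random holdout split
#'
#' Draws `ceiling(fraction * class size)` genomes per label class into the
#' holdout, deterministically for a seed.
#'
#' @param genome_ids Character vector of ids.
#' @param labels `"HL"`/`"LL"` labels aligned with `genome_ids`.
#' @param fraction Holdout fraction in (0, 1).
#' @param seed Integer seed.
#' @return List with `train_ids` and `holdout_ids`.
#' @export
split_holdout <- function(genome_ids, labels, fraction = 0.2, seed = 1L) {
  stopifnot(length(genome_ids) == length(labels),
            fraction > 0, fraction < 1)
  tab <- table(labels)
  if (any(tab < 2L)) stop("each class needs >= 2 members", call. = FALSE)
  holdout <- with_seed(seed, {
    unlist(lapply(names(tab), function(cl) {
      ids <- genome_ids[labels == cl]
      sample(ids, ceiling(fraction * length(ids)))
    }), use.names = FALSE)
  })
  list(train_ids = setdiff(genome_ids, holdout), holdout_ids = holdout)
}

# stage output g(x) for standardized feature matrix x
stage_forward <- function(stage, x) {
  h <- tanh(sweep(x %*% stage$a, 2L, stage$c, `+`))
  drop(h %*% stage$v) + stage$b0
}

ensemble_logit <- function(model, x) {
  f <- rep(model$f0, nrow(x))
  for (st in model$stages) f <- f + model$learning_rate * stage_forward(st, x)
  f
}

pack_stage <- function(stage) c(as.vector(stage$a), stage$c, stage$v, stage$b0)
unpack_stage <- function(par, p, h) {
  list(a = matrix(par[seq_len(p * h)], p, h),
       c = par[p * h + seq_len(h)],
       v = par[p * h + h + seq_len(h)],
       b0 = par[p * h + 2L * h + 1L])
}

# one boosting stage: penalized ML logistic fit of the shrunk contribution
# offset + lr * g(x), so the learning rate is part of the stage objective
fit_stage <- function(x, y, offset, h, lambda, lr, max_iter, init_sd = 0.5) {
  p <- ncol(x)
  npar <- p * h + 2L * h + 1L
  par0 <- stats::rnorm(npar, sd = init_sd)

  nll <- function(par) {
    st <- unpack_stage(par, p, h)
    f <- offset + lr * stage_forward(st, x)
    # log(1 + exp(f)) - y*f, computed stably
    loss <- sum(ifelse(f > 0, f + log1p(exp(-f)), log1p(exp(f))) - y * f)
    loss + lambda * sum(par[-npar]^2)
  }
  grad <- function(par) {
    st <- unpack_stage(par, p, h)
    z <- sweep(x %*% st$a, 2L, st$c, `+`)
    t_ <- tanh(z)
    f <- offset + lr * (drop(t_ %*% st$v) + st$b0)
    r <- lr * (stats::plogis(f) - y)
    d <- t_ * 0
    for (j in seq_len(h)) d[, j] <- r * st$v[j] * (1 - t_[, j]^2)
    g <- c(as.vector(crossprod(x, d)), colSums(d), colSums(t_ * r), sum(r))
    g + 2 * lambda * c(par[-npar], 0)
  }
  opt <- stats::optim(par0, nll, grad, method = "BFGS",
                      control = list(maxit = max_iter))
  if (opt$value > nll(par0) + 1e-8) {
    stop(sprintf("stage optimization diverged (start %.4g, end %.4g)",
                 nll(par0), opt$value), call. = FALSE)
  }
  unpack_stage(opt$par, p, h)
}

#' Fit the boosted TanH ecotype classifier
#'
#' Trains a boosted additive ensemble of small single-hidden-layer TanH
#' networks on domain-abundance features to predict the HL/LL label. A
#' stratified holdout is removed before fitting; covariates are
#' z-standardized with training-set statistics. Each stage is a penalized
#' maximum-likelihood logistic fit of a `hidden_nodes`-TanH network given
#' the running ensemble logit as offset; its contribution is shrunk by the
#' learning rate before the next stage is fit. The ensemble logit is the
#' base-rate logit plus the scaled stage outputs; class probabilities are
#' its logistic transform.
#'
#' @param features Numeric matrix, genomes x features, with rownames.
#' @param labels Named `"HL"`/`"LL"` vector covering the rows, or an
#'   unnamed vector aligned with them.
#' @param config An [ann_config()].
#' @param holdout Optional precomputed split (list with `train_ids`,
#'   `holdout_ids`); by default drawn via [split_holdout()] with the config
#'   seed.
#' @return An `ann_boost` model. Its `report` element holds `train_r2`,
#'   `valid_r2` (entropy R-squared, one minus the deviance ratio),
#'   `train_misclass`, `valid_misclass`, `holdout_ids`.
#' @export
ann_fit <- function(features, labels, config = ann_config(), holdout = NULL) {
  stopifnot(is.matrix(features), !is.null(rownames(features)))
  if (!is.null(names(labels))) labels <- labels[rownames(features)]
  stopifnot(length(labels) == nrow(features), all(labels %in% c("HL", "LL")))
  names(labels) <- rownames(features)

  single_class <- length(unique(labels)) == 1L
  if (is.null(holdout)) {
    holdout <- if (single_class) {
      # no stratified split is possible; validate on the training data
      list(train_ids = rownames(features), holdout_ids = character())
    } else {
      split_holdout(rownames(features), labels, config$holdout_fraction,
                    config$seed)
    }
  }
  tr <- holdout$train_ids
  ho <- holdout$holdout_ids

  xtr_raw <- features[tr, , drop = FALSE]
  mu <- colMeans(xtr_raw)
  sds <- apply(xtr_raw, 2L, stats::sd)
  if (!config$standardize) { mu[] <- 0; sds[] <- 1 }
  sds[sds == 0] <- 1
  xtr <- sweep(sweep(xtr_raw, 2L, mu), 2L, sds, `/`)
  y <- as.numeric(labels[tr] == "HL")

  n <- length(y)
  f0 <- stats::qlogis((sum(y) + 0.5) / (n + 1))
  f <- rep(f0, n)
  stages <- with_seed(config$seed, {
    out <- vector("list", config$n_models)
    for (t_ in seq_len(config$n_models)) {
      st <- fit_stage(xtr, y, f, config$hidden_nodes, config$penalty_lambda,
                      config$learning_rate, config$max_iter)
      f <- f + config$learning_rate * stage_forward(st, xtr)
      out[[t_]] <- st
    }
    out
  })

  model <- structure(list(stages = stages, f0 = f0,
                          learning_rate = config$learning_rate,
                          feature_means = mu, feature_sds = sds,
                          feature_names = colnames(features),
                          classes = c("HL", "LL"), config = config),
                     class = "ann_boost")
  model$report <- c(
    fit_metrics(model, features[tr, , drop = FALSE], labels[tr], "train"),
    if (length(ho) > 0L) {
      fit_metrics(model, features[ho, , drop = FALSE], labels[ho], "valid")
    } else {
      list(valid_r2 = NA_real_, valid_misclass = NA_real_)
    },
    list(holdout_ids = ho)
  )
  model
}

fit_metrics <- function(model, features, labels, prefix) {
  p <- predict(model, features, type = "prob")[, "HL"]
  y <- as.numeric(labels == "HL")
  eps <- 1e-12
  pc <- pmin(pmax(p, eps), 1 - eps)
  dev <- -2 * sum(y * log(pc) + (1 - y) * log(1 - pc))
  p0 <- min(max(mean(y), eps), 1 - eps)
  dev0 <- -2 * sum(y * log(p0) + (1 - y) * log(1 - p0))
  r2 <- if (dev0 > 0) 1 - dev / dev0 else 1
  mis <- mean((p >= 0.5) != (y == 1))
  stats::setNames(list(r2, mis), paste0(prefix, c("_r2", "_misclass")))
}

#' Predict from a boosted TanH model
#'
#' @param object An `ann_boost` model.
#' @param newdata Numeric matrix with the training feature columns.
#' @param type `"prob"` (n x 2 matrix of HL/LL probabilities summing to 1
#'   per row), `"class"`, or `"logit"`.
#' @param ... Unused.
#' @return Probabilities, class labels, or logits.
#' @export
predict.ann_boost <- function(object, newdata, type = c("prob", "class", "logit"), ...) {
  type <- match.arg(type)
  stopifnot(is.matrix(newdata))
  if (ncol(newdata) != length(object$feature_names)) {
    stop(sprintf("feature count mismatch: model has %d, newdata has %d",
                 length(object$feature_names), ncol(newdata)), call. = FALSE)
  }
  if (!is.null(colnames(newdata)) &&
      !identical(colnames(newdata), object$feature_names)) {
    newdata <- newdata[, object$feature_names, drop = FALSE]
  }
  x <- sweep(sweep(newdata, 2L, object$feature_means), 2L, object$feature_sds, `/`)
  f <- ensemble_logit(object, x)
  if (type == "logit") return(f)
  p_hl <- stats::plogis(f)
  if (type == "class") {
    return(ifelse(p_hl >= 0.5, "HL", "LL"))
  }
  cbind(HL = p_hl, LL = 1 - p_hl)
}

#' @export
print.ann_boost <- function(x, ...) {
  r <- x$report
  cat(sprintf(paste0(
    "ann_boost: %d stages x %d TanH nodes, learning rate %g\n",
    "  train R2 %.4f, misclass %.3f; holdout (n=%d) R2 %s, misclass %s\n"),
    x$config$n_models, x$config$hidden_nodes, x$learning_rate,
    r$train_r2, r$train_misclass, length(r$holdout_ids),
    ifelse(is.na(r$valid_r2), "NA", sprintf("%.4f", r$valid_r2)),
    ifelse(is.na(r$valid_misclass), "NA", sprintf("%.3f", r$valid_misclass))))
  invisible(x)
}

#' Variance-based (Sobol) variable importance
#'
#' Main effect = first-order Sobol index, total effect = total Sobol index
#' of each feature on the predicted HL probability, estimated by Monte
#' Carlo with features resampled independently from their empirical
#' marginals (Saltelli/Jansen pick-freeze estimators). Negative estimates,
#' which arise only from Monte-Carlo noise, are clamped to zero.
#'
#' @param model An `ann_boost`.
#' @param features Feature matrix supplying the empirical marginals.
#' @param n_mc Monte-Carlo base-sample size (>= 100).
#' @param seed Integer seed.
#' @return Data frame with `feature`, `main_effect`, `total_effect`.
#' @export
variable_importance <- function(model, features, n_mc = 2000L, seed = 1L) {
  stopifnot(inherits(model, "ann_boost"), is.matrix(features))
  if (n_mc < 100L) stop("n_mc < 100 gives unstable Sobol estimates", call. = FALSE)
  p <- ncol(features)
  pred <- function(x) predict(model, x, type = "prob")[, "HL"]
  with_seed(seed, {
    draw <- function() {
      vapply(seq_len(p),
             function(j) sample(features[, j], n_mc, replace = TRUE),
             numeric(n_mc))
    }
    a <- draw(); b <- draw()
    colnames(a) <- colnames(b) <- colnames(features)
    ya <- pred(a); yb <- pred(b)
    v <- stats::var(c(ya, yb))
    main <- total <- numeric(p)
    if (v > 0) {
      for (j in seq_len(p)) {
        ab <- a; ab[, j] <- b[, j]
        yab <- pred(ab)
        main[j] <- mean(yb * (yab - ya)) / v        # Saltelli/Janon first-order
        total[j] <- mean((ya - yab)^2) / (2 * v)    # Jansen total
      }
    }
    data.frame(feature = colnames(features),
               main_effect = pmax(main, 0), total_effect = pmax(total, 0),
               stringsAsFactors = FALSE)
  })
}

#' Marginal (partial-dependence) profile of one feature
#'
#' Average predicted HL probability over the data as the chosen feature is
#' swept across a grid spanning its observed range, with every other
#' feature left at its observed values.
#'
#' @param model An `ann_boost`.
#' @param features Feature matrix (the data to average over).
#' @param feature Column index or name.
#' @param grid_size Number of grid points.
#' @return Data frame with `value` and `prob_hl`.
#' @export
marginal_profile <- function(model, features, feature, grid_size = 25L) {
  stopifnot(inherits(model, "ann_boost"), is.matrix(features))
  if (is.character(feature)) feature <- match(feature, colnames(features))
  stopifnot(!is.na(feature), feature >= 1L, feature <= ncol(features))
  rng <- range(features[, feature])
  if (rng[1L] == rng[2L]) {
    warning("constant feature; single-point profile")
    grid <- rng[1L]
  } else {
    grid <- seq(rng[1L], rng[2L], length.out = grid_size)
  }
  prob <- vapply(grid, function(g) {
    x <- features
    x[, feature] <- g
    mean(predict(model, x, type = "prob")[, "HL"])
  }, numeric(1L))
  data.frame(value = grid, prob_hl = prob)
}

#' @export
plot.ann_boost <- function(x, features, which = seq_len(min(4L, ncol(features))), ...) {
  old <- graphics::par(mfrow = grDevices::n2mfrow(length(which)))
  on.exit(graphics::par(old))
  for (j in which) {
    pr <- marginal_profile(x, features, j)
    graphics::plot(pr$value, pr$prob_hl, type = "l", ylim = c(0, 1),
                   xlab = colnames(features)[j], ylab = "P(HL)", ...)
  }
  invisible(x)
}
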