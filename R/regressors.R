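# Regression backends for the bias estimators.
#
# Four regression types are supported, all at library defaults except the
# tree ensembles, which use 1000 trees:
#   linear - ordinary least squares (stats::lm machinery, stored as plain
#            coefficients)
#   lsvr   - epsilon-SVR with a linear kernel (e1071::svm, scale = FALSE so
#            that constant-feature intercept-only fits are well defined)
#   rfr    - random forest regression (ranger, 1000 trees)
#   etr    - extremely randomised trees (ranger, splitrule "extratrees",
#            no bootstrap resampling, 1000 trees)
# mtry is the full feature count for the tree ensembles (the conventional
# regression default); all fits are single-threaded and seeded, so results
# are reproducible bit-for-bit.

regression_types <- function() c("linear", "lsvr", "rfr", "etr")

fit_regressor <- function(x, y, type, seed = 1L) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (nrow(x) != length(y)) abort_config("regressor design and response lengths differ")
  if (ncol(x) == 0L) x <- matrix(1, nrow = length(y), ncol = 1L)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))

  if (diff(range(y)) == 0) {
    # degenerate response: every regression type reduces to the constant
    # (and SMO-based SVR has no support vectors to return at all)
    return(structure(list(type = "const", n_features = ncol(x),
                          feature_names = colnames(x), fit = list(value = y[1])),
                     class = "t1stand_regressor"))
  }
  fit <- switch(
    type,
    linear = {
      X <- cbind(`(Intercept)` = 1, x)
      co <- stats::lm.fit(X, y)$coefficients
      co[is.na(co)] <- 0
      list(coef = co)
    },
    # epsilon 0 (the linear-SVR convention): the default 0.1-wide tube would
    # swallow relative bias targets, which live on a fractional scale
    lsvr = e1071::svm(x = x, y = y, kernel = "linear", scale = FALSE, epsilon = 0),
    rfr = {
      d <- data.frame(y = y, x)
      ranger::ranger(y ~ ., data = d, num.trees = 1000L, mtry = ncol(x),
                     seed = seed, num.threads = 1L)
    },
    etr = {
      d <- data.frame(y = y, x)
      ranger::ranger(y ~ ., data = d, num.trees = 1000L, mtry = ncol(x),
                     splitrule = "extratrees", replace = FALSE, sample.fraction = 1,
                     seed = seed, num.threads = 1L)
    },
    abort_config(paste0("unknown regression type: ", type))
  )
  structure(list(type = type, n_features = ncol(x), feature_names = colnames(x), fit = fit),
            class = "t1stand_regressor")
}

predict_regressor <- function(model, x) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (ncol(x) == 0L) x <- matrix(1, nrow = nrow(x), ncol = 1L)
  colnames(x) <- model$feature_names
  switch(
    model$type,
    const = rep(model$fit$value, nrow(x)),
    linear = as.numeric(cbind(1, x) %*% model$fit$coef),
    lsvr = as.numeric(stats::predict(model$fit, x)),
    as.numeric(stats::predict(model$fit, data.frame(x), num.threads = 1L)$predictions)
  )
}
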