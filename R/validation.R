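# External validation statistics. Conventions:
#  * r2_pred = 1 - PRESS/SD, PRESS over the test set, SD relative to the
#    TRAINING mean (the external-predictivity statistic).
#  * Through-origin r0^2 values: 1 - SS_res/SS_tot of the DEPENDENT
#    variable, with the through-origin slope of the dependent on the
#    independent. r0^2 takes dep = predicted, indep = observed; the primed
#    variant swaps the axes.
#  * rm2 metrics are computed on min-max scaled vectors by default.

#' Prediction residuals
#'
#' @param actual,predicted Equal-length numeric vectors.
#' @return `actual - predicted`.
#' @export
prediction_residuals <- function(actual, predicted) {
  if (length(actual) != length(predicted)) {
    abort("actual and predicted must have equal length")
  }
  actual - predicted
}

#' External predictive r2 (r2_pred)
#'
#' `r2_pred = 1 - PRESS/SD` where `PRESS = sum((yhat_test - y_test)^2)` and
#' `SD = sum((y_test - mean(y_train))^2)`: the improvement of the model's
#' test-set predictions over the no-model baseline that predicts every test
#' compound at the training mean.
#'
#' @param y_test,yhat_test Observed and predicted test activities
#'   (length >= 2).
#' @param y_train Observed training activities (non-empty).
#' @return Tibble with `r2_pred`, `press`, `sd`, `train_mean`, `n_test`.
#' @export
r2_pred <- function(y_test, yhat_test, y_train) {
  if (length(y_test) != length(yhat_test)) {
    abort("test vectors must have equal length")
  }
  if (length(y_test) < 2L) abort("need at least 2 test compounds")
  if (length(y_train) == 0L) abort("empty training activities")
  press <- sum((yhat_test - y_test)^2)
  sd_ <- sum((y_test - mean(y_train))^2)
  if (sd_ <= 0) abort("degenerate test set: zero deviation from train mean")
  tibble(r2_pred = 1 - press / sd_, press = press, sd = sd_,
         train_mean = mean(y_train), n_test = length(y_test))
}

# through-origin regression of dep on indep:
# slope k = sum(dep*indep)/sum(indep^2);
# r0^2 = 1 - sum((dep - k*indep)^2) / sum((dep - mean(dep))^2)
.r0_sq <- function(dep, indep) {
  k <- sum(dep * indep) / sum(indep^2)
  1 - sum((dep - k * indep)^2) / sum((dep - mean(dep))^2)
}

#' Golbraikh-Tropsha external-validation criteria
#'
#' Computes the Pearson r2 between observed and predicted, the
#' through-origin slopes `k = sum(y*yhat)/sum(yhat^2)` (observed on
#' predicted) and `k' = sum(y*yhat)/sum(y^2)` (predicted on observed), the
#' through-origin determination coefficients `r0_sq` (dep = predicted,
#' indep = observed) and `r0_prime_sq` (axes swapped), and the four
#' acceptability flags:
#' (i) `q2 > 0.5`; (ii) `r2 > 0.6`;
#' (iii) `(r2 - r0_sq)/r2 < 0.1` with `0.85 <= k <= 1.15`, or the primed
#' analogue with `k'`; (iv) `|r0_sq - r0_prime_sq| < 0.3`.
#'
#' @param y,yhat Observed and predicted activities (length >= 3,
#'   non-constant).
#' @param q2 Cross-validated q2 of the underlying model (used by flag i).
#' @return One-row tibble with the statistics, individual flags
#'   `pass_q2`, `pass_r2`, `pass_slope`, `pass_r0_gap`, and `pass_all`.
#' @export
golbraikh_tropsha <- function(y, yhat, q2) {
  if (length(y) != length(yhat)) abort("y and yhat must have equal length")
  if (length(y) < 3L) abort("need at least 3 compounds")
  if (!isTRUE(var(y) > 0) || !isTRUE(var(yhat) > 0)) {
    abort("zero-variance input")
  }
  r2 <- cor(y, yhat)^2
  k <- sum(y * yhat) / sum(yhat^2)
  k_prime <- sum(y * yhat) / sum(y^2)
  r0 <- .r0_sq(dep = yhat, indep = y)
  r0p <- .r0_sq(dep = y, indep = yhat)
  pass_q2 <- q2 > 0.5
  pass_r2 <- r2 > 0.6
  pass_slope <- ((r2 - r0) / r2 < 0.1 && k >= 0.85 && k <= 1.15) ||
    ((r2 - r0p) / r2 < 0.1 && k_prime >= 0.85 && k_prime <= 1.15)
  pass_r0_gap <- abs(r0 - r0p) < 0.3
  tibble(r2 = r2, r0_sq = r0, r0_prime_sq = r0p, k = k, k_prime = k_prime,
         q2 = q2,
         pass_q2 = pass_q2, pass_r2 = pass_r2, pass_slope = pass_slope,
         pass_r0_gap = pass_r0_gap,
         pass_all = pass_q2 && pass_r2 && pass_slope && pass_r0_gap)
}

#' rm2 external-validation metrics
#'
#' Roy's rm2 metrics: `rm2 = r2 * (1 - sqrt(r2 - r0_sq))` and the primed
#' variant with `r0_prime_sq`; reported alongside their average and
#' absolute difference. Acceptability guidance: average > 0.5 and delta
#' < 0.2. With `scaled = TRUE` (default) both vectors are first min-max
#' scaled to \[0, 1\] using their own extrema; Pearson r2 is unchanged by
#' that scaling but the through-origin quantities are not. A negative
#' radicand (possible when r0_sq exceeds r2 numerically) is clamped to zero
#' with a warning.
#'
#' @inheritParams golbraikh_tropsha
#' @param scaled Min-max scale `y` and `yhat` before computing the metrics.
#' @return One-row tibble with `rm2`, `rm2_prime`, `rm2_avg`, `rm2_delta`,
#'   `scaled`.
#' @export
rm2_metrics <- function(y, yhat, scaled = TRUE) {
  if (length(y) != length(yhat)) abort("y and yhat must have equal length")
  if (length(y) < 3L) abort("need at least 3 compounds")
  if (scaled) {
    rngy <- range(y); rngh <- range(yhat)
    if (diff(rngy) == 0 || diff(rngh) == 0) {
      abort("constant vector: min-max scaling is degenerate")
    }
    y <- (y - rngy[1]) / diff(rngy)
    yhat <- (yhat - rngh[1]) / diff(rngh)
  }
  if (!isTRUE(var(y) > 0) || !isTRUE(var(yhat) > 0)) {
    abort("zero-variance input")
  }
  r2 <- cor(y, yhat)^2
  r0 <- .r0_sq(dep = yhat, indep = y)
  r0p <- .r0_sq(dep = y, indep = yhat)
  rad <- c(r2 - r0, r2 - r0p)
  if (any(rad < -1e-12)) {
    warn("negative (r2 - r0^2) radicand clamped to zero")
  }
  rad <- pmax(rad, 0)
  rm2 <- r2 * (1 - sqrt(rad[1]))
  rm2p <- r2 * (1 - sqrt(rad[2]))
  tibble(rm2 = rm2, rm2_prime = rm2p,
         rm2_avg = (rm2 + rm2p) / 2, rm2_delta = abs(rm2 - rm2p),
         scaled = scaled)
}

#' Externally validate a fitted hologram QSAR model
#'
#' Predicts the `role == "test"` compounds, then assembles the full
#' external-validation report: per-compound residuals, [r2_pred()] against
#' the training mean, the [golbraikh_tropsha()] criteria (using the model's
#' LOO q2), and [rm2_metrics()].
#'
#' @param model An `hqsar_model` from [hqsar_train()].
#' @param data Compound tibble containing the test rows (defaults to
#'   requiring `role == "test"` rows with observed activity).
#' @param scaled_rm2 Compute rm2 metrics on min-max scaled values.
#' @return An object of class `hqsar_validation` with elements
#'   `residuals` (tibble id/actual/predicted/residual), `r2_pred`, `gt`,
#'   `rm2`.
#' @export
hqsar_validate <- function(model, data, scaled_rm2 = TRUE) {
  stopifnot(inherits(model, "hqsar_model"))
  data <- validate_dataset(data)
  test <- data[data$role == "test", ]
  if (nrow(test) == 0L) abort("no test compounds (role == 'test')")
  pred <- predict(model, test)
  stopifnot(identical(pred$id, test$id))
  res <- tibble(id = test$id, actual = test$pic50,
                predicted = pred$predicted,
                residual = prediction_residuals(test$pic50, pred$predicted))
  structure(
    list(
      residuals = res,
      r2_pred = r2_pred(test$pic50, pred$predicted, model$train$pic50),
      gt = golbraikh_tropsha(test$pic50, pred$predicted, model$pls$q2),
      rm2 = rm2_metrics(test$pic50, pred$predicted, scaled = scaled_rm2)
    ),
    class = "hqsar_validation"
  )
}

#' @export
print.hqsar_validation <- function(x, ...) {
  cat("<hqsar_validation> external validation,",
      nrow(x$residuals), "test compounds\n")
  cat(sprintf("  r2_pred = %.4f (PRESS = %.4f, SD = %.4f)\n",
              x$r2_pred$r2_pred, x$r2_pred$press, x$r2_pred$sd))
  cat(sprintf("  Golbraikh-Tropsha: r2 = %.4f, all pass: %s\n",
              x$gt$r2, x$gt$pass_all))
  cat(sprintf("  rm2 avg = %.4f, delta = %.4f (%s)\n",
              x$rm2$rm2_avg, x$rm2$rm2_delta,
              if (x$rm2$scaled) "scaled" else "unscaled"))
  invisible(x)
}

#' @export
tidy.hqsar_validation <- function(x, ...) x$residuals

#' @export
glance.hqsar_validation <- function(x, ...) {
  dplyr::bind_cols(
    x$r2_pred[, c("r2_pred", "press", "sd")],
    x$gt[, c("r2", "r0_sq", "r0_prime_sq", "k", "k_prime", "pass_all")],
    x$rm2[, c("rm2_avg", "rm2_delta")]
  )
}
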