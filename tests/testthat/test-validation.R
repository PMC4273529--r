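ref_pairs <- function() {
  ref <- mmp12_reference()
  list(test = ref[ref$role == "test", ], train = ref[ref$role == "train", ])
}

test_that("residuals are observed minus predicted", {
  rp <- ref_pairs()$test
  expect_equal(prediction_residuals(3.1549, 2.688), 0.4669)
  expect_equal(prediction_residuals(2.0969, 2.502), -0.4051)
  expect_equal(prediction_residuals(rp$actual_pic50, rp$actual_pic50),
               rep(0, 9))
  expect_error(prediction_residuals(1:3, 1:2), "equal length")
})

test_that("r2_pred implements 1 - PRESS/SD against the training mean", {
  y_tr <- c(1, 2, 3, 4)
  y_te <- c(1.5, 2.5, 3.5)
  # perfect predictions
  expect_equal(r2_pred(y_te, y_te, y_tr)$r2_pred, 1)
  # predicting the training mean everywhere gives exactly zero
  base <- rep(mean(y_tr), 3)
  expect_equal(r2_pred(y_te, base, y_tr)$r2_pred, 0)
  # reference table pairs (training mean 2.7477)
  rp <- ref_pairs()
  got <- r2_pred(rp$test$actual_pic50, rp$test$predicted_pic50,
                 rp$train$actual_pic50)
  expect_equal(got$press, 0.32236444, tolerance = 1e-8)
  expect_equal(got$sd, 2.66012404, tolerance = 1e-8)
  expect_equal(got$r2_pred, 0.87881601, tolerance = 1e-8)
  # invariance under a common additive shift
  s <- 1.7
  shifted <- r2_pred(rp$test$actual_pic50 + s,
                     rp$test$predicted_pic50 + s,
                     rp$train$actual_pic50 + s)
  expect_equal(shifted$r2_pred, got$r2_pred, tolerance = 1e-12)
  expect_error(r2_pred(c(2, 2), c(1, 3), c(2, 2)), "degenerate")
  expect_error(r2_pred(1:3, 1:2, 1:4), "equal length")
})

test_that("Golbraikh-Tropsha criteria pass on perfect and fail on scrambled", {
  y <- c(1, 1.5, 2.2, 3, 3.6, 4.1)
  gt <- golbraikh_tropsha(y, y, q2 = 1)
  expect_equal(gt$r2, 1)
  expect_equal(gt$r0_sq, 1)
  expect_equal(gt$r0_prime_sq, 1)
  expect_equal(gt$k, 1)
  expect_equal(gt$k_prime, 1)
  expect_true(gt$pass_all)
  # uncorrelated predictions fail the r2 > 0.6 condition
  set.seed(8)
  scr <- golbraikh_tropsha(y, y[c(4, 6, 1, 5, 2, 3)], q2 = 1)
  expect_false(scr$pass_r2)
  expect_false(scr$pass_all)
  # anti-correlated predictions fail too (r2 high but slope negative ->
  # through-origin fits collapse)
  anti <- golbraikh_tropsha(y, max(y) + min(y) - y, q2 = 1)
  expect_false(anti$pass_all)
  expect_error(golbraikh_tropsha(y, rep(2, 6), 1), "zero-variance")
  # reference table pairs: all four conditions hold with the published q2
  rp <- ref_pairs()
  gref <- golbraikh_tropsha(rp$test$actual_pic50, rp$test$predicted_pic50,
                            q2 = 0.697)
  expect_equal(gref$r2, 0.85942595, tolerance = 1e-8)
  expect_true(gref$pass_all)
})

test_that("rm2 metrics match a step-by-step spreadsheet oracle", {
  y <- c(0, 1, 2, 3); yh <- c(0.1, 0.9, 2.2, 2.8)
  # independent recomputation, spelled out term by term (unscaled)
  r2 <- (sum((y - mean(y)) * (yh - mean(yh))) /
           sqrt(sum((y - mean(y))^2) * sum((yh - mean(yh))^2)))^2
  k_dep_pred <- sum(yh * y) / sum(y^2)    # pred regressed on obs
  r0 <- 1 - sum((yh - k_dep_pred * y)^2) / sum((yh - mean(yh))^2)
  k_dep_obs <- sum(y * yh) / sum(yh^2)    # obs regressed on pred
  r0p <- 1 - sum((y - k_dep_obs * yh)^2) / sum((y - mean(y))^2)
  want_rm2 <- r2 * (1 - sqrt(max(0, r2 - r0)))
  want_rm2p <- r2 * (1 - sqrt(max(0, r2 - r0p)))
  got <- rm2_metrics(y, yh, scaled = FALSE)
  expect_equal(got$rm2, want_rm2, tolerance = 1e-10)
  expect_equal(got$rm2_prime, want_rm2p, tolerance = 1e-10)
  expect_equal(got$rm2_avg, (want_rm2 + want_rm2p) / 2, tolerance = 1e-10)
  expect_equal(got$rm2_delta, abs(want_rm2 - want_rm2p), tolerance = 1e-10)
  # identity on perfect predictions
  gp <- rm2_metrics(y, y, scaled = TRUE)
  expect_equal(gp$rm2, 1)
  expect_equal(gp$rm2_delta, 0)
  # reference table pairs, scaled convention
  rp <- ref_pairs()
  gref <- rm2_metrics(rp$test$actual_pic50, rp$test$predicted_pic50)
  expect_equal(gref$rm2_avg, 0.6978977434, tolerance = 1e-8)
  expect_equal(gref$rm2_delta, 0.1350152769, tolerance = 1e-8)
  expect_error(rm2_metrics(c(1, 1, 1), c(1, 2, 3)), "constant")
})

test_that("min-max scaling changes through-origin quantities but not r2", {
  y <- c(1.2, 2.1, 2.9, 3.4, 4.2); yh <- c(1.1, 2.4, 2.7, 3.6, 3.9)
  un <- rm2_metrics(y, yh, scaled = FALSE)
  sc <- rm2_metrics(y, yh, scaled = TRUE)
  gt_un <- golbraikh_tropsha(y, yh, 1)
  sc_y <- (y - min(y)) / diff(range(y))
  sc_yh <- (yh - min(yh)) / diff(range(yh))
  gt_sc <- golbraikh_tropsha(sc_y, sc_yh, 1)
  expect_equal(gt_un$r2, gt_sc$r2, tolerance = 1e-12) # Pearson invariant
  expect_false(isTRUE(all.equal(gt_un$r0_sq, gt_sc$r0_sq)))
  expect_false(isTRUE(all.equal(gt_un$k, gt_sc$k)))
  expect_false(isTRUE(all.equal(un$rm2, sc$rm2)))
})

test_that("model validation assembles the full external report", {
  fit <- recovery_model()
  series <- recovery_series()
  val <- hqsar_validate(fit, series)
  expect_s3_class(val, "hqsar_validation")
  expect_identical(nrow(val$residuals), sum(series$role == "test"))
  expect_equal(val$residuals$residual,
               val$residuals$actual - val$residuals$predicted)
  expect_gt(val$r2_pred$r2_pred, 0.7) # low-noise synthetic series
  # glance/tidy surface
  gl <- glance(val)
  expect_true(all(c("r2_pred", "r2", "rm2_avg", "pass_all") %in% names(gl)))
  expect_identical(tidy(val), val$residuals)
  # no test compounds -> error
  expect_error(hqsar_validate(fit, dplyr::filter(series, role == "train")),
               "no test")
})

test_that("validating the model on its own training rows is definitional", {
  fit <- recovery_model()
  series <- recovery_series()
  # relabel training compounds as test: press/sd identity means r2_pred
  # equals 1 - SS_res/SS_tot of the fit on those compounds
  fake <- dplyr::mutate(recovery_series(), role = "test")
  fake <- fake[series$role == "train", ]
  val <- hqsar_validate(fit, fake)
  ss_res <- sum((fit$train$pic50 - fit$train$fitted)^2)
  ss_tot <- sum((fit$train$pic50 - mean(fit$train$pic50))^2)
  expect_equal(val$r2_pred$r2_pred, 1 - ss_res / ss_tot, tolerance = 1e-10)
})
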