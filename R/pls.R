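# PLS1 regression engine. Hologram counts share a unit, so predictors are
# mean-centred but not variance-scaled. NIPALS extracts orthogonal score
# vectors; coefficients are back-transformed to the original bin space so a
# fitted model is a plain linear rule over bin counts.

#' Fit a PLS regression model
#'
#' NIPALS partial least squares with a single response. `X` is
#' mean-centred (no variance scaling) and `y` centred; `ncomp` latent
#' components are extracted and the coefficient vector is back-transformed
#' to the original descriptor space. Reported statistics: `r2 = 1 -
#' SS_res/SS_tot` on the training data and `see = sqrt(SS_res / (n - ncomp
#' - 1))`.
#'
#' @param X Numeric matrix, observations in rows.
#' @param y Numeric response, `length(y) == nrow(X)`, non-constant.
#' @param ncomp Number of latent components (>= 1); must not exceed the
#'   rank of the centred `X`, and `nrow(X) >= ncomp + 2`.
#' @return An object of class `hqsar_pls` with elements `coefficients`,
#'   `intercept`, `ncomp`, `r2`, `see`, `fitted`, plus `q2`/`sep` slots
#'   (`NA` until filled by [loo_cv()] callers).
#' @seealso [loo_cv()], [select_components()]
#' @export
fit_pls <- function(X, y, ncomp) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  n <- nrow(X); p <- ncol(X)
  ncomp <- as.integer(ncomp)
  if (length(y) != n) abort("length(y) must equal nrow(X)")
  if (ncomp < 1L) abort("ncomp must be >= 1")
  if (n < ncomp + 2L) abort("need at least ncomp + 2 observations")
  if (!isTRUE(var(y) > 0)) abort("constant response: nothing to fit")

  x_means <- colMeans(X)
  y_mean <- mean(y)
  E <- sweep(X, 2L, x_means)
  f <- y - y_mean

  W <- matrix(0, p, ncomp)
  P <- matrix(0, p, ncomp)
  Q <- numeric(ncomp)
  for (h in seq_len(ncomp)) {
    w <- drop(crossprod(E, f))
    wn <- sqrt(sum(w^2))
    if (wn < 1e-12) {
      abort(paste0("ncomp = ", ncomp, " exceeds the rank of the centred ",
                   "predictor matrix (exhausted at component ", h - 1L, ")"))
    }
    w <- w / wn
    t <- drop(E %*% w)
    tt <- sum(t^2)
    if (tt < 1e-12) {
      abort(paste0("degenerate score vector at component ", h))
    }
    p_h <- drop(crossprod(E, t)) / tt
    q_h <- sum(f * t) / tt
    E <- E - tcrossprod(t, p_h)
    f <- f - q_h * t
    W[, h] <- w; P[, h] <- p_h; Q[h] <- q_h
  }
  # back-transform: B = W (P'W)^{-1} q
  B <- drop(W %*% solve(crossprod(P, W), Q))
  intercept <- y_mean - sum(x_means * B)
  fitted <- unname(drop(X %*% B)) + intercept
  ss_res <- sum((y - fitted)^2)
  ss_tot <- sum((y - y_mean)^2)
  structure(
    list(
      coefficients = setNames(B, colnames(X)),
      intercept = intercept,
      ncomp = ncomp,
      r2 = 1 - ss_res / ss_tot,
      see = sqrt(ss_res / (n - ncomp - 1)),
      q2 = NA_real_, sep = NA_real_,
      fitted = fitted, n = n, y_mean = y_mean
    ),
    class = "hqsar_pls"
  )
}

#' @export
predict.hqsar_pls <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$coefficients)) {
    abort("newdata has wrong number of descriptors for this model")
  }
  unname(drop(newdata %*% object$coefficients)) + object$intercept
}

#' @export
print.hqsar_pls <- function(x, ...) {
  cat("<hqsar_pls> ", x$ncomp, " component(s), n = ", x$n, "\n",
      sprintf("  r2 = %.4f  see = %.4f", x$r2, x$see), "\n", sep = "")
  if (!is.na(x$q2)) {
    cat(sprintf("  q2 = %.4f  sep = %.4f (LOO)\n", x$q2, x$sep))
  }
  invisible(x)
}

#' @export
tidy.hqsar_pls <- function(x, ...) {
  tibble(term = c("(Intercept)",
                  names(x$coefficients) %||%
                    paste0("bin", seq_along(x$coefficients))),
         estimate = c(x$intercept, unname(x$coefficients)))
}

#' @export
glance.hqsar_pls <- function(x, ...) {
  tibble(n = x$n, ncomp = x$ncomp, r2 = x$r2, see = x$see,
         q2 = x$q2, sep = x$sep)
}

#' Leave-one-out cross-validation of a PLS model
#'
#' For each observation, refits the model on the remaining `n - 1` rows and
#' predicts the held-out response. `q2 = 1 - PRESS / sum((y - mean(y))^2)`
#' with the full-data mean, and `sep = sqrt(PRESS / (n - ncomp - 1))`.
#'
#' @inheritParams fit_pls
#' @return A list with `q2`, `sep`, and `predictions` (the LOO predictions
#'   in row order).
#' @export
loo_cv <- function(X, y, ncomp) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 3L) abort("leave-one-out needs at least 3 observations")
  if (ncomp >= n - 1L) abort("ncomp must be < n - 1 for leave-one-out")
  preds <- numeric(n)
  for (i in seq_len(n)) {
    fit <- fit_pls(X[-i, , drop = FALSE], y[-i], ncomp)
    preds[i] <- predict(fit, X[i, , drop = FALSE])
  }
  press <- sum((y - preds)^2)
  list(
    q2 = 1 - press / sum((y - mean(y))^2),
    sep = sqrt(press / (n - ncomp - 1)),
    predictions = preds
  )
}

#' Select the number of PLS components by LOO q2
#'
#' Runs [loo_cv()] for `1..max_ncomp` components and picks the count
#' maximising q2, breaking ties toward fewer components.
#'
#' @inheritParams fit_pls
#' @param max_ncomp Largest component count to try. Counts beyond the rank
#'   of (any leave-one-out subset of) the centred predictors truncate the
#'   table rather than failing, so rank-deficient designs are handled.
#' @return A list with `ncomp_opt` and `table`, a tibble of
#'   `(ncomp, q2, sep)`.
#' @export
select_components <- function(X, y, max_ncomp = 6L) {
  max_ncomp <- as.integer(max_ncomp)
  if (max_ncomp < 1L) abort("max_ncomp must be >= 1")
  rows <- vector("list", max_ncomp)
  for (c_try in seq_len(max_ncomp)) {
    cv <- tryCatch(loo_cv(X, y, c_try), error = function(e) {
      if (c_try > 1L && grepl("rank|degenerate", conditionMessage(e))) {
        NULL
      } else {
        abort(conditionMessage(e))
      }
    })
    if (is.null(cv)) break
    rows[[c_try]] <- tibble(ncomp = c_try, q2 = cv$q2, sep = cv$sep)
  }
  tab <- dplyr::bind_rows(rows)
  best <- which.max(tab$q2) # first maximum -> smallest ncomp on ties
  list(ncomp_opt = tab$ncomp[best], table = tab)
}
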