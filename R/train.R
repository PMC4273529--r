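# Model search over the hologram-length catalogue. Fragmentation does not
# depend on the length, so fragments are enumerated once and only re-binned
# per candidate length; each length gets its own LOO component selection.

#' Train a hologram QSAR model across a length catalogue
#'
#' For every hologram length in the configuration: featurize the training
#' compounds, pick the component count by LOO q2 ([select_components()]),
#' and record cross-validated (q2, sep) and fitted (r2, see) statistics.
#' The best model is the one with maximal q2 (ties toward the smaller
#' length). Ensemble statistics are the arithmetic means of r2 and see over
#' the per-length models — the collection of per-length models is the
#' "ensemble".
#'
#' @param data Compound tibble (see [read_compound_table()]); rows with
#'   `role == "train"` are used for fitting.
#' @param config A [hologram_config()].
#' @param max_components Largest component count tried per length.
#' @return An object of class `hqsar_model`: the best `hqsar_pls` fit
#'   (`$pls`, with `q2`/`sep` filled in), `$length`, `$config`,
#'   `$per_length` tibble, `$ensemble_r2`, `$ensemble_see`,
#'   `$component_table` for the best length, and the training data with
#'   fitted and LOO predictions (`$train`).
#' @examples
#' \donttest{
#' series <- generate_series(series_spec(seed = 7))
#' fit <- hqsar_train(series, hologram_config(lengths = c(53, 97)))
#' glance(fit)
#' }
#' @export
hqsar_train <- function(data, config = hologram_config(),
                        max_components = 6L) {
  data <- validate_dataset(data)
  train <- data[data$role == "train", ]
  if (nrow(train) == 0L) abort("no training compounds (role == 'train')")
  y <- train$pic50
  frag_keys <- dataset_fragments(train, config)
  max_c <- min(as.integer(max_components), nrow(train) - 2L)

  lengths <- sort(config$lengths)
  rows <- vector("list", length(lengths))
  sel_best <- NULL
  for (j in seq_along(lengths)) {
    L <- lengths[j]
    X <- hologram_matrix(frag_keys, L)
    sel <- select_components(X, y, max_c)
    cv <- sel$table[sel$table$ncomp == sel$ncomp_opt, ]
    fit <- fit_pls(X, y, sel$ncomp_opt)
    rows[[j]] <- tibble(length = L, ncomp = sel$ncomp_opt,
                        q2 = cv$q2, sep = cv$sep,
                        r2 = fit$r2, see = fit$see)
    rows[[j]]$.sel <- list(sel)
  }
  per_length <- dplyr::bind_rows(rows)
  best_j <- which.max(per_length$q2) # lengths ascending -> smaller L on tie
  best_L <- per_length$length[best_j]
  component_table <- per_length$.sel[[best_j]]$table
  per_length$.sel <- NULL

  Xb <- hologram_matrix(frag_keys, best_L)
  pls <- fit_pls(Xb, y, per_length$ncomp[best_j])
  cvb <- loo_cv(Xb, y, pls$ncomp)
  pls$q2 <- cvb$q2
  pls$sep <- cvb$sep

  train$fitted <- pls$fitted
  train$loo_pred <- cvb$predictions
  structure(
    list(
      pls = pls,
      length = best_L,
      config = config,
      per_length = per_length,
      ensemble_r2 = mean(per_length$r2),
      ensemble_see = mean(per_length$see),
      component_table = component_table,
      train = train,
      frag_keys = frag_keys,
      max_components = max_c
    ),
    class = "hqsar_model"
  )
}

#' @export
print.hqsar_model <- function(x, ...) {
  cat("<hqsar_model> hologram QSAR model\n",
      "  best length: ", x$length, "  components: ", x$pls$ncomp, "\n",
      sprintf("  q2 = %.4f  sep = %.4f  r2 = %.4f  see = %.4f\n",
              x$pls$q2, x$pls$sep, x$pls$r2, x$pls$see),
      sprintf("  ensemble (mean over %d lengths): r2 = %.4f  see = %.4f\n",
              nrow(x$per_length), x$ensemble_r2, x$ensemble_see),
      sep = "")
  invisible(x)
}

#' @export
tidy.hqsar_model <- function(x, ...) x$per_length

#' @export
glance.hqsar_model <- function(x, ...) {
  tibble(length = x$length, ncomp = x$pls$ncomp,
         q2 = x$pls$q2, sep = x$pls$sep,
         r2 = x$pls$r2, see = x$pls$see,
         ensemble_r2 = x$ensemble_r2, ensemble_see = x$ensemble_see,
         n_train = nrow(x$train))
}

#' Predict activities for new compounds
#'
#' Featurizes `newdata` at the model's hologram length and configuration
#' and applies the fitted linear rule.
#'
#' @param object An `hqsar_model`.
#' @param newdata Compound tibble with `id` and `smiles`.
#' @param ... Unused.
#' @return Tibble with `id` and `predicted` pIC50.
#' @export
predict.hqsar_model <- function(object, newdata, ...) {
  X <- featurize_dataset(newdata, object$config, object$length)
  tibble(id = rownames(X), predicted = predict(object$pls, X))
}

#' Y-randomization of a fitted model
#'
#' Refits the model at the selected hologram length and component count
#' after randomly permuting the training activities, leaving the
#' descriptors untouched. A real structure-activity signal should collapse:
#' shuffled q2 and r2 are expected to be far below the unshuffled values.
#' Each run uses the derived seed `seed + run` so the whole experiment is
#' reproducible from one integer.
#'
#' @param model An `hqsar_model`.
#' @param n_runs Number of shuffles.
#' @param seed Base seed.
#' @param permute_fn Optional function `n -> permutation` overriding the
#'   seeded random shuffle (testing hook; e.g. `identity ordering`).
#' @return An object of class `hqsar_yrand`: tibble of
#'   `(run, seed, q2, r2)` with the real model's `q2`/`r2` as attributes.
#' @export
y_randomize <- function(model, n_runs = 5L, seed = 1L, permute_fn = NULL) {
  stopifnot(inherits(model, "hqsar_model"))
  n_runs <- as.integer(n_runs)
  if (n_runs < 1L) abort("n_runs must be >= 1")
  X <- hologram_matrix(model$frag_keys, model$length)
  y <- model$train$pic50
  n <- length(y)
  rows <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    run_seed <- as.integer(seed) + r
    perm <- if (is.null(permute_fn)) {
      withr::with_seed(run_seed, sample.int(n))
    } else {
      permute_fn(n)
    }
    ys <- y[perm]
    fit <- fit_pls(X, ys, model$pls$ncomp)
    cv <- loo_cv(X, ys, model$pls$ncomp)
    rows[[r]] <- tibble(run = r, seed = run_seed, q2 = cv$q2, r2 = fit$r2)
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "real_q2") <- model$pls$q2
  attr(out, "real_r2") <- model$pls$r2
  class(out) <- c("hqsar_yrand", class(out))
  out
}

#' @export
print.hqsar_yrand <- function(x, ...) {
  cat("Y-randomization:", nrow(x), "shuffled refits",
      sprintf("(real q2 = %.3f, r2 = %.3f)\n",
              attr(x, "real_q2"), attr(x, "real_r2")))
  print(as_tibble(x))
  invisible(x)
}
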