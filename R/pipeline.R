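# End-to-end pipeline: load -> train -> Y-randomize -> validate -> AD ->
# contributions -> predict, writing a self-describing report bundle.
# Every numeric report carries the definition of its statistics, and the
# seed appears in every file, so a rerun with the same configuration
# produces byte-identical JSON/CSV artifacts.

.write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = TRUE)
}

#' Run the full hologram QSAR pipeline
#'
#' Loads a compound table (path or tibble), trains the hologram-length
#' model search on the `train` rows, runs Y-randomization, validates on the
#' `test` rows (if any), scores the applicability domain, computes per-atom
#' contribution tables, and predicts `role == "predict"` compounds with a
#' standard error of prediction. The SE of prediction for a new compound is
#' the model's LOO standard error inflated by its applicability-domain
#' score: `sep * (1 + max(0, score))`, so compounds farther from the
#' training set carry a larger stated uncertainty (the formula is recorded
#' in the output).
#'
#' @param input Path to a compound CSV ([read_compound_table()]) or a
#'   compound tibble.
#' @param out_dir Output directory (created if needed).
#' @param config A [hologram_config()].
#' @param max_components Largest PLS component count tried.
#' @param yrand_runs Number of Y-randomization shuffles (0 to skip).
#' @param seed Seed for the Y-randomization shuffles.
#' @param contributions Write per-atom contribution tables.
#' @return Invisibly, a list with the fitted `model`, `validation` (or
#'   `NULL`), `yrand`, `ad`, `predictions`, and the written file paths.
#' @export
run_hqsar_pipeline <- function(input, out_dir,
                               config = hologram_config(),
                               max_components = 6L,
                               yrand_runs = 5L,
                               seed = 1L,
                               contributions = TRUE) {
  data <- if (is.character(input)) read_compound_table(input) else
    validate_dataset(as_tibble(input))
  if (!"smiles" %in% names(data) || anyNA(data$smiles)) {
    abort("pipeline input needs structures (smiles) for every record")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  log_lines <- c(paste0("hqsar pipeline, package version ",
                        as.character(utils::packageVersion("hqsar"))),
                 paste0("seed: ", seed),
                 paste0("records: ", nrow(data), " (",
                        sum(data$role == "train"), " train, ",
                        sum(data$role == "test"), " test, ",
                        sum(data$role == "predict"), " predict)"))

  model <- hqsar_train(data, config, max_components)
  log_lines <- c(log_lines,
                 sprintf("best length %d, %d components, q2 = %.4f",
                         model$length, model$pls$ncomp, model$pls$q2))

  paths$model <- file.path(out_dir, "model.json")
  .write_json(list(
    definitions = list(
      q2 = "1 - PRESS_LOO / SS_tot, leave-one-out",
      see = "sqrt(SS_res / (n - ncomp - 1)) on the training fit",
      sep = "sqrt(PRESS_LOO / (n - ncomp - 1))",
      ensemble = "arithmetic mean of r2/see over the per-length models"
    ),
    seed = seed,
    config = list(lengths = config$lengths, frag_min = config$frag_min,
                  frag_max = config$frag_max,
                  distinctions = config$distinctions),
    length = model$length, ncomp = model$pls$ncomp,
    intercept = model$pls$intercept,
    coefficients = unname(model$pls$coefficients),
    q2 = model$pls$q2, sep = model$pls$sep,
    r2 = model$pls$r2, see = model$pls$see,
    ensemble_r2 = model$ensemble_r2, ensemble_see = model$ensemble_see
  ), paths$model)

  paths$search <- file.path(out_dir, "search.csv")
  readr::write_csv(model$per_length, paths$search, progress = FALSE)

  yrand <- NULL
  if (yrand_runs > 0L) {
    yrand <- y_randomize(model, n_runs = yrand_runs, seed = seed)
    paths$yrand <- file.path(out_dir, "yrandomization.csv")
    readr::write_csv(as_tibble(yrand), paths$yrand, progress = FALSE)
    log_lines <- c(log_lines,
                   sprintf("y-randomization: max shuffled q2 = %.4f",
                           max(yrand$q2)))
  }

  validation <- NULL
  if (any(data$role == "test")) {
    validation <- hqsar_validate(model, data)
    paths$validation <- file.path(out_dir, "validation.json")
    .write_json(list(
      definitions = list(
        r2_pred = "1 - PRESS_test / SD, SD about the training mean",
        r0_sq = paste("through-origin determination coefficient of the",
                      "dependent (r0: dep = predicted; r0': dep = observed),",
                      "slope = dependent-on-independent through origin"),
        rm2 = "r2 * (1 - sqrt(r2 - r0_sq)), on min-max scaled values",
        k = "sum(y*yhat)/sum(yhat^2); k' with axes swapped"
      ),
      seed = seed,
      r2_pred = as.list(validation$r2_pred),
      golbraikh_tropsha = as.list(validation$gt),
      rm2 = as.list(validation$rm2)
    ), paths$validation)
    paths$residuals <- file.path(out_dir, "residuals.csv")
    readr::write_csv(validation$residuals, paths$residuals, progress = FALSE)
    log_lines <- c(log_lines,
                   sprintf("external validation: r2_pred = %.4f",
                           validation$r2_pred$r2_pred))
  }

  ad <- applicability_domain(model, data)
  paths$ad <- file.path(out_dir, "ad_scores.csv")
  ad_out <- ad
  ad_out$score <- round(ad_out$score, 4L)
  readr::write_csv(ad_out, paths$ad, progress = FALSE)

  if (contributions) {
    paths$contributions <- file.path(out_dir, "contributions.csv")
    readr::write_csv(contribution_table(model, data), paths$contributions,
                     progress = FALSE)
  }

  predictions <- NULL
  if (any(data$role == "predict")) {
    newd <- data[data$role == "predict", ]
    pr <- predict(model, newd)
    sc <- ad$score[match(newd$id, ad$id)]
    predictions <- tibble(
      id = pr$id, predicted_pic50 = pr$predicted,
      se_prediction = model$pls$sep * (1 + pmax(0, sc)),
      distance_score = round(sc, 4L),
      in_domain = ad$in_domain[match(newd$id, ad$id)]
    )
    paths$predictions <- file.path(out_dir, "predictions.csv")
    readr::write_csv(predictions, paths$predictions, progress = FALSE)
    log_lines <- c(log_lines,
                   paste0("predicted ", nrow(predictions),
                          " designed compound(s); se = sep*(1+max(0,score))"))
  }

  paths$log <- file.path(out_dir, "pipeline.log")
  writeLines(log_lines, paths$log)
  message(paste(log_lines, collapse = "\n"))
  invisible(list(model = model, validation = validation, yrand = yrand,
                 ad = ad, predictions = predictions, paths = paths))
}

#' Read a pipeline run configuration from YAML
#'
#' Supported keys: `input`, `out_dir`, `max_components`, `yrand_runs`,
#' `seed`, `contributions`, and any of the [hologram_config()] fields
#' under `hologram:`.
#'
#' @param path YAML file.
#' @return A named list of arguments for [run_hqsar_pipeline()].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[intersect(names(y), c("input", "out_dir", "max_components",
                                  "yrand_runs", "seed", "contributions"))]
  if (!is.null(y$hologram)) {
    args$config <- do.call(hologram_config, y$hologram)
  }
  args
}
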