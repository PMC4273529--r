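# Atomic contribution maps. Every fragment occurrence carries the model
# coefficient of its hologram bin; that weight is split equally among the
# fragment's heavy atoms and accumulated per atom, so the atom values sum
# exactly to the molecule's linear fragment term (prediction minus
# intercept). The colour mapping follows the conventional seven-band
# red-to-green vocabulary: warm colours for negative contributions, grey
# for near-zero, yellow-to-green for positive.

.contribution_colors <- c("red", "red_orange", "orange", "gray_white",
                          "yellow", "green_blue", "green")

#' Map atom contribution values to colour bands
#'
#' Values within `threshold_frac * max(|value|)` of zero are `gray_white`.
#' More negative values pass through `orange`, `red_orange`, `red` (equal-
#' width magnitude bands up to the most negative value); more positive
#' values through `yellow`, `green_blue`, `green`. The mapping is monotone:
#' a larger value never gets a redder colour.
#'
#' @param values Numeric vector of per-atom contributions.
#' @param threshold_frac Half-width of the neutral band as a fraction of
#'   the largest absolute value.
#' @return Ordered factor with levels from `red` to `green`.
#' @export
color_bins <- function(values, threshold_frac = 0.05) {
  if (length(values) == 0L) abort("no values to colour")
  out <- rep("gray_white", length(values))
  m <- max(abs(values))
  if (m > 0) {
    t <- threshold_frac * m
    neg <- values < -t
    pos <- values > t
    band <- function(mag, top) {
      # 1..3 equal-width magnitude bands on (t, top]
      pmin(3L, pmax(1L, ceiling(3 * (mag - t) / (top - t))))
    }
    if (any(neg)) {
      top <- max(-values[neg])
      if (top <= t) {
        out[neg] <- "orange"
      } else {
        out[neg] <- c("orange", "red_orange", "red")[band(-values[neg], top)]
      }
    }
    if (any(pos)) {
      top <- max(values[pos])
      if (top <= t) {
        out[pos] <- "yellow"
      } else {
        out[pos] <- c("yellow", "green_blue", "green")[band(values[pos], top)]
      }
    }
  }
  factor(out, levels = .contribution_colors, ordered = TRUE)
}

#' Per-atom contributions of a molecule under a fitted model
#'
#' Enumerates the molecule's fragments with the model's configuration,
#' looks up each occurrence's hologram-bin coefficient, splits it equally
#' among the fragment's heavy atoms, and accumulates per atom. The column
#' `value` sums exactly to the molecule's fragment term
#' `prediction - intercept`.
#'
#' @param model An `hqsar_model`.
#' @param smiles A single SMILES string (optionally named with the
#'   compound id).
#' @param threshold_frac Passed to [color_bins()].
#' @return An object of class `hqsar_contribution`: a tibble with `atom`,
#'   `element`, `value`, `color`, with attributes `total` (sum of values)
#'   and `prediction`.
#' @export
atom_contributions <- function(model, smiles, threshold_frac = 0.05) {
  stopifnot(inherits(model, "hqsar_model"))
  if (length(smiles) != 1L) abort("one molecule at a time")
  mol <- parse_molecules(smiles)[[1]]
  frags <- enumerate_fragments(mol, model$config)
  values <- numeric(mol$n)
  coefs <- model$pls$coefficients
  L <- model$length
  total <- 0
  if (length(frags) > 0L) {
    keys <- vapply(frags, fragment_key, character(1),
                   mol = mol, distinctions = model$config$distinctions)
    bins <- .bin_of_key(keys, L)
    for (i in seq_along(frags)) {
      w <- coefs[[bins[i]]]
      atoms <- frags[[i]]
      values[atoms] <- values[atoms] + w / length(atoms)
      total <- total + w
    }
  }
  out <- tibble(atom = seq_len(mol$n), element = mol$elements,
                value = values,
                color = color_bins(values, threshold_frac))
  attr(out, "total") <- sum(values)
  attr(out, "prediction") <- total + model$pls$intercept
  attr(out, "id") <- names(smiles) %||% NA_character_
  class(out) <- c("hqsar_contribution", class(out))
  out
}

#' Contribution table for several compounds
#'
#' @param model An `hqsar_model`.
#' @param data Compound tibble with `id` and `smiles`.
#' @return One long tibble: `id`, `atom`, `element`, `value`, `color`.
#' @export
contribution_table <- function(model, data) {
  data <- validate_dataset(data, require_activity = FALSE)
  purrr::map_dfr(seq_len(nrow(data)), function(i) {
    cm <- atom_contributions(model, setNames(data$smiles[i], data$id[i]))
    dplyr::mutate(as_tibble(cm), id = data$id[i], .before = 1L)
  })
}
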