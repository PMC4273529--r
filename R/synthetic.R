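# Synthetic congeneric series with known fragment-additive activity.
# The generator emulates the statistical shape of the study series -- one
# shared scaffold, varying R-groups, ~35 compounds, pIC50 spanning about
# three log units with a 26/9 activity-stratified train/test split -- not
# the (figure-only) chemistry of the real inhibitors. Activities are built
# from weights on canonical fragment keys, so by construction the truth is
# exactly the fragment-additive model the hologram pipeline assumes, plus
# Gaussian noise.

# default R-group catalogue: the named substituents of the reference table
# plus common small alkyl/ether/halide/aryl variations, 35 in all. Ring
# closures use digit 3 to avoid clashing with the scaffold's open rings.
.default_r_groups <- c(
  Methyl = "C", Ethyl = "CC", `n-Propyl` = "CCC", `i-Propyl` = "C(C)C",
  `n-Butyl` = "CCCC", `t-Butyl` = "C(C)(C)C", `i-Butyl` = "CC(C)C",
  `s-Butyl` = "C(C)CC", `n-Pentyl` = "CCCCC", Neopentyl = "CC(C)(C)C",
  CH2OCH3 = "COC", CH2CH2OCH3 = "CCOC", Methoxy = "OC", Ethoxy = "OCC",
  Hydroxyl = "O", Amino = "N", Dimethylamino = "N(C)C", Aminomethyl = "CN",
  CF3 = "C(F)(F)F", CH2F = "CF", F = "F", Cl = "Cl", Br = "Br",
  Cyclopropyl = "C3CC3", Cyclobutyl = "C3CCC3", Cyclopentyl = "C3CCCC3",
  Cyclohexyl = "C3CCCCC3", CH2Cyclopropyl = "CC3CC3",
  Phenyl = "c3ccccc3", Benzyl = "Cc3ccccc3", `4-Tolyl` = "c3ccc(C)cc3",
  Vinyl = "C=C", Allyl = "CC=C", Propargyl = "CC#C", Acetyl = "C(C)=O"
)

#' Specification of a synthetic congeneric series
#'
#' The scaffold is a dibenzofuran-like fused tricycle bearing a carboxylic
#' acid (a generic stand-in with one substitution point, written as a
#' SMILES template containing the literal token `{R}`). Activity of each
#' compound is `base + sum over fragment occurrences of fragment_weights`
#' plus `N(0, noise_sd)` noise. When `fragment_weights` is `NULL`
#' (default), weights are drawn for a seeded random subset of the series'
#' fragment keys and rescaled so the noise-free activities span
#' `activity_range` — mirroring the roughly three-log-unit span of the
#' study series.
#'
#' @param scaffold_smiles SMILES template with one `{R}` attachment token.
#' @param r_groups Named character vector of R-group SMILES fragments.
#' @param base_activity Baseline pIC50 added to every compound when
#'   explicit `fragment_weights` are supplied.
#' @param fragment_weights Optional named numeric vector mapping canonical
#'   fragment keys to activity weights; `NULL` draws them.
#' @param n_weighted_keys Number of fragment keys given a nonzero drawn
#'   weight (auto-weight mode). Candidates are keys occurring in at least
#'   `min_support` compounds but not in all of them: activity must ride on
#'   recurring, discriminating substructures — a fragment seen in a single
#'   compound cannot inform the prediction of any held-out compound, and a
#'   fragment common to every compound only shifts the baseline. The
#'   default 12 emulates a series whose potency is set by a dozen
#'   substructural features.
#' @param min_support Minimum number of compounds a candidate weighted key
#'   must occur in.
#' @param activity_range Target noise-free pIC50 span (auto-weight mode).
#' @param noise_sd Gaussian noise on pIC50. The default 0.15 log unit is a
#'   typical inter-assay reproducibility for IC50 measurements.
#' @param seed Integer seed driving weight draw, noise, and nothing else.
#' @param n_train,n_test Sizes of the activity-stratified split; compounds
#'   beyond `n_train + n_test` get `role = "predict"`.
#' @param config [hologram_config()] used to enumerate the fragments that
#'   carry activity.
#' @return A list of class `series_spec`.
#' @export
series_spec <- function(scaffold_smiles = "OC(=O)c1ccc2c(c1)oc1ccc({R})cc12",
                        r_groups = .default_r_groups,
                        base_activity = 2.7,
                        fragment_weights = NULL,
                        n_weighted_keys = 12L,
                        min_support = 3L,
                        activity_range = c(1.6383, 4.0),
                        noise_sd = 0.15,
                        seed = 1L,
                        n_train = 26L, n_test = 9L,
                        config = hologram_config()) {
  if (!grepl("{R}", scaffold_smiles, fixed = TRUE)) {
    abort("scaffold_smiles must contain one '{R}' attachment token")
  }
  if (length(r_groups) == 0L) abort("need at least one R-group")
  if (is.null(names(r_groups)) || any(!nzchar(names(r_groups)))) {
    abort("r_groups must be named")
  }
  if (noise_sd < 0) abort("noise_sd must be >= 0")
  n_train <- as.integer(n_train); n_test <- as.integer(n_test)
  if (n_train + n_test > length(r_groups)) {
    abort("n_train + n_test exceeds the number of compounds")
  }
  structure(
    list(scaffold_smiles = scaffold_smiles, r_groups = r_groups,
         base_activity = base_activity,
         fragment_weights = fragment_weights,
         n_weighted_keys = as.integer(n_weighted_keys),
         min_support = as.integer(min_support),
         activity_range = activity_range, noise_sd = noise_sd,
         seed = as.integer(seed), n_train = n_train, n_test = n_test,
         config = config),
    class = "series_spec"
  )
}

# evenly spaced interior ranks for the test subset: mirrors a split chosen
# for uniform coverage of the activity range
.stratified_roles <- function(pic50, n_train, n_test) {
  n <- length(pic50)
  ord <- order(pic50)
  role <- rep("predict", n)
  test_pos <- integer(0)
  if (n_test > 0L) {
    raw <- round(seq(2, n - 1, length.out = n_test))
    test_pos <- unique(pmin(pmax(raw, 1L), n))
    cand <- setdiff(seq_len(n), test_pos)
    while (length(test_pos) < n_test) { # top up after rounding collisions
      test_pos <- c(test_pos, cand[1L]); cand <- cand[-1L]
    }
  }
  rest <- setdiff(seq_len(n), test_pos)
  train_pos <- rest[round(seq(1, length(rest), length.out = n_train))]
  role[ord[test_pos]] <- "test"
  role[ord[train_pos]] <- "train"
  role
}

#' Generate a synthetic congeneric series
#'
#' Builds one compound per R-group by splicing the group into the scaffold
#' template, assigns fragment-additive activities plus seeded Gaussian
#' noise, and splits compounds into train/test by activity-stratified
#' ranks. The generating truth (effective fragment weights, base, seed) is
#' attached as the `"generator"` attribute so tests can recompute it.
#'
#' @param spec A [series_spec()].
#' @return Compound tibble (`id`, `r_group`, `smiles`, `ic50_um`, `pic50`,
#'   `role`, `source`) ready for [hqsar_train()].
#' @examples
#' \donttest{
#' series <- generate_series(series_spec(seed = 42, noise_sd = 0))
#' activity_summary(series, "train")
#' }
#' @export
generate_series <- function(spec = series_spec()) {
  stopifnot(inherits(spec, "series_spec"))
  ids <- names(spec$r_groups)
  smiles <- vapply(spec$r_groups, function(r) {
    sub("{R}", r, spec$scaffold_smiles, fixed = TRUE)
  }, character(1))
  mols <- tryCatch(parse_molecules(setNames(smiles, ids)),
                   error = function(e) {
                     abort(paste0("invalid scaffold/R-group chemistry: ",
                                  conditionMessage(e)))
                   })
  key_list <- lapply(seq_along(mols), function(i) {
    .molecule_keys(mols[[i]], spec$config, cache_id = smiles[i])
  })

  if (is.null(spec$fragment_weights)) {
    # Candidate keys: recurring but discriminating (present in at least
    # min_support compounds, absent from at least one). A key unique to a
    # single compound cannot inform prediction of held-out compounds; a
    # key present everywhere only shifts the baseline.
    n_cmp <- length(key_list)
    support <- table(unlist(lapply(key_list, unique)))
    cand <- sort(names(support)[support >= spec$min_support &
                                support < n_cmp])
    if (length(cand) == 0L) {
      abort("no fragment key recurs across compounds; cannot draw weights")
    }
    count_of <- function(key) {
      vapply(key_list, function(k) sum(k == key), numeric(1))
    }
    sel <- withr::with_seed(spec$seed, {
      shuffled <- sample(cand)
      # greedy: prefer keys that split compounds with identical weighted-
      # fragment profiles, so activities are distinct by construction
      profile <- rep("", n_cmp)
      chosen <- character(0)
      for (key in shuffled) {
        if (length(unique(profile)) == n_cmp) break
        prof2 <- paste(profile, count_of(key))
        if (length(unique(prof2)) > length(unique(profile))) {
          chosen <- c(chosen, key)
          profile <- prof2
        }
      }
      extra <- setdiff(shuffled, chosen)
      n_fill <- max(0L, spec$n_weighted_keys - length(chosen))
      c(chosen, head(extra, n_fill))
    })
    counts <- vapply(sel, count_of, numeric(n_cmp))
    # integer weight palette: distinct profiles map to integer-spaced raw
    # activity levels, keeping recovery checks sharp; redraw (seeded) if
    # two distinct profiles collide on the same weighted sum
    palette <- c(-3L, -2L, -1L, 1L, 2L, 3L)
    prof_str <- apply(counts, 1L, paste, collapse = ",")
    raw <- NULL
    for (attempt in 0:24) {
      w_int <- withr::with_seed(spec$seed + 100L * attempt, {
        sample(palette, length(sel), replace = TRUE)
      })
      raw <- drop(counts %*% w_int)
      # distinct fragment profiles should map to distinct activity levels
      if (length(unique(raw)) == length(unique(prof_str))) break
    }
    rng <- range(raw)
    if (diff(rng) > 0) {
      a <- diff(spec$activity_range) / diff(rng)
      b <- spec$activity_range[1] - a * rng[1]
    } else {
      a <- 1; b <- mean(spec$activity_range) - rng[1]
    }
    weights <- setNames(w_int * a, sel)
    base <- b
  } else {
    weights <- spec$fragment_weights
    base <- spec$base_activity
  }
  signal <- base +
    vapply(key_list, function(k) sum(weights[k], na.rm = TRUE), numeric(1))
  noise <- if (spec$noise_sd > 0) {
    withr::with_seed(spec$seed + 1L, rnorm(length(signal), 0, spec$noise_sd))
  } else {
    numeric(length(signal))
  }
  pic50 <- signal + noise
  out <- tibble(
    id = ids, r_group = unname(spec$r_groups), smiles = unname(smiles),
    ic50_um = pic50_to_ic50(pic50), pic50 = pic50,
    role = .stratified_roles(pic50, spec$n_train, spec$n_test),
    source = "synthetic"
  )
  attr(out, "generator") <- list(weights = weights, base = base,
                                 signal = signal, noise_sd = spec$noise_sd,
                                 seed = spec$seed, config = spec$config)
  out
}

.reference_crc32 <- 1707176489

#' Reference activity table of the MMP-12 inhibitor series
#'
#' The packaged observed/predicted activity table of the dibenzofuran
#' MMP-12 inhibitor case study: 26 training and 9 test compounds with
#' observed pIC50 (micromolar scale), the published model's predicted
#' pIC50, the printed residuals, and normalized mean-distance
#' applicability-domain scores (one training-set score is missing in the
#' source and is `NA`). Structures of the series exist only as published
#' drawings, so this table carries activities and roles, not SMILES.
#' The file's CRC-32 is verified on load.
#'
#' @param path Alternate file to read (used for integrity checks); default
#'   is the packaged table.
#' @return Tibble with columns `id`, `r_group`, `actual_pic50`,
#'   `predicted_pic50`, `residual`, `role`, `distance_score`.
#' @examples
#' ref <- mmp12_reference()
#' table(ref$role) # 26 train, 9 test
#' @export
mmp12_reference <- function(path = NULL) {
  path <- path %||% system.file("extdata", "mmp12_reference.csv",
                                package = "hqsar", mustWork = TRUE)
  raw <- readBin(path, "raw", n = file.size(path))
  if (crc32(rawToChar(raw)) != .reference_crc32) {
    abort("reference table is corrupted (checksum mismatch)")
  }
  out <- readr::read_csv(
    path,
    col_types = readr::cols(
      id = "c", r_group = "c", actual_pic50 = "d", predicted_pic50 = "d",
      residual = "d", role = "c", distance_score = "d"
    ),
    progress = FALSE
  )
  stopifnot(sum(out$role == "train") == 26L, sum(out$role == "test") == 9L)
  out
}
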