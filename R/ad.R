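# Euclidean normalized-mean-distance applicability domain. Descriptor
# columns are standardized on the training set (constant columns dropped);
# each training compound's mean distance to the OTHER training compounds is
# min-max normalized to [0, 1]. External compounds are scored with the mean
# distance over ALL training rows under the training normalization; a score
# outside [0, 1] puts the compound outside the domain.

#' Fit an applicability-domain model
#'
#' @param X_train Numeric descriptor matrix (>= 3 rows, at least one
#'   non-constant column), e.g. a hologram matrix.
#' @return An object of class `hqsar_ad` with the standardization
#'   (`center`, `scale`, `keep`), the training distances (`d`, `d_min`,
#'   `d_max`) and normalized `train_scores`.
#' @export
fit_ad <- function(X_train) {
  X_train <- as.matrix(X_train)
  n <- nrow(X_train)
  if (n < 3L) abort("applicability domain needs at least 3 training rows")
  ctr <- colMeans(X_train)
  scl <- apply(X_train, 2L, sd)
  keep <- which(scl > 0)
  if (length(keep) == 0L) abort("all descriptor columns are constant")
  Z <- sweep(sweep(X_train[, keep, drop = FALSE], 2L, ctr[keep]),
             2L, scl[keep], "/")
  D <- as.matrix(stats::dist(Z))
  d <- unname(rowSums(D)) / (n - 1L) # mean distance excluding self
  d_min <- min(d); d_max <- max(d)
  if (d_max - d_min <= 0) {
    abort("degenerate training set: all mean distances identical")
  }
  structure(
    list(center = ctr[keep], scale = scl[keep], keep = keep, p = ncol(X_train),
         Z = Z, d = d, d_min = d_min, d_max = d_max,
         train_scores = (d - d_min) / (d_max - d_min),
         ids = rownames(X_train)),
    class = "hqsar_ad"
  )
}

#' @export
print.hqsar_ad <- function(x, ...) {
  cat("<hqsar_ad> Euclidean normalized mean distance,",
      nrow(x$Z), "training compounds,", ncol(x$Z), "descriptors\n",
      sprintf("  raw distance range: [%.4f, %.4f]\n", x$d_min, x$d_max))
  invisible(x)
}

#' Score compounds against an applicability domain
#'
#' @param ad An `hqsar_ad` from [fit_ad()].
#' @param X Descriptor matrix (or single vector) in the original,
#'   unstandardized space, with the training column dimension.
#' @return Tibble with `score` and `in_domain` (`0 <= score <= 1`), one row
#'   per row of `X`.
#' @export
score_ad <- function(ad, X) {
  stopifnot(inherits(ad, "hqsar_ad"))
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  X <- as.matrix(X)
  if (ncol(X) != ad$p) {
    abort("descriptor dimension does not match the training matrix")
  }
  Z <- sweep(sweep(X[, ad$keep, drop = FALSE], 2L, ad$center),
             2L, ad$scale, "/")
  scores <- vapply(seq_len(nrow(Z)), function(i) {
    di <- sqrt(rowSums(sweep(ad$Z, 2L, Z[i, ])^2))
    (mean(di) - ad$d_min) / (ad$d_max - ad$d_min)
  }, numeric(1))
  tibble(score = scores, in_domain = scores >= 0 & scores <= 1)
}

#' Applicability-domain report for a dataset
#'
#' Fits the domain on the model's training holograms (at the selected
#' length) and scores every compound in `data`. Training compounds get
#' their leave-self-out training scores; other roles are scored as external
#' queries.
#'
#' @param model An `hqsar_model`.
#' @param data Compound tibble; defaults to the model's training set only.
#' @return Tibble with `id`, `role`, `score`, `in_domain`.
#' @export
applicability_domain <- function(model, data = NULL) {
  stopifnot(inherits(model, "hqsar_model"))
  Xtr <- hologram_matrix(model$frag_keys, model$length)
  ad <- fit_ad(Xtr)
  train_tbl <- tibble(id = model$train$id, role = "train",
                      score = ad$train_scores,
                      in_domain = TRUE)
  if (is.null(data)) return(train_tbl)
  data <- validate_dataset(data, require_activity = FALSE)
  ext <- data[data$role != "train", ]
  out <- train_tbl[train_tbl$id %in% data$id, ]
  if (nrow(ext) > 0L) {
    Xe <- featurize_dataset(ext, model$config, model$length)
    sc <- score_ad(ad, Xe)
    out <- dplyr::bind_rows(
      out,
      tibble(id = ext$id, role = ext$role,
             score = sc$score, in_domain = sc$in_domain)
    )
  }
  out[match(intersect(data$id, out$id), out$id), ]
}
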