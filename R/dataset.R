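# Compound tables. A dataset is an ordinary tibble with columns
#   id (chr), smiles (chr), ic50_um (dbl), pic50 (dbl), role (chr), source (chr)
# so every verb in dplyr works on it directly. Activities live on the
# micromolar scale throughout: pIC50 = -log10(IC50 in uM).

.roles <- c("train", "test", "predict")

#' Convert IC50 (micromolar) to pIC50
#'
#' @param ic50 Positive numeric vector of IC50 values in micromolar.
#' @param id Optional ids used in error messages.
#' @return `-log10(ic50)`.
#' @examples
#' to_pic50(1)      # 0
#' to_pic50(1e-4)   # 4
#' @export
to_pic50 <- function(ic50, id = NULL) {
  bad <- is.na(ic50) | ic50 <= 0
  if (any(bad)) {
    who <- if (!is.null(id)) paste(id[bad], collapse = ", ") else
      paste(which(bad), collapse = ", ")
    abort(paste0("IC50 must be positive and present; offending record(s): ",
                 who))
  }
  -log10(ic50)
}

#' Convert pIC50 back to IC50 (micromolar)
#'
#' Inverse of [to_pic50()].
#' @param pic50 Numeric vector.
#' @return `10^(-pic50)`, in micromolar.
#' @export
pic50_to_ic50 <- function(pic50) 10^(-pic50)

# Internal: check/complete a compound tibble. Fills pic50 from ic50_um (and
# vice versa), enforces id uniqueness, role values, and activity presence.
validate_dataset <- function(data, require_activity = TRUE) {
  data <- as_tibble(data)
  if (!"id" %in% names(data)) {
    abort("compound table needs an 'id' column")
  }
  data$id <- as.character(data$id)
  if (anyDuplicated(data$id)) {
    abort(paste0("duplicate compound id(s): ",
                 paste(unique(data$id[duplicated(data$id)]), collapse = ", ")))
  }
  if (!"role" %in% names(data)) data$role <- "train"
  if (!all(data$role %in% .roles)) {
    abort(paste0("role must be one of ", paste(.roles, collapse = "/")))
  }
  if (!"ic50_um" %in% names(data)) data$ic50_um <- NA_real_
  if (!"pic50" %in% names(data)) data$pic50 <- NA_real_
  fill <- is.na(data$pic50) & !is.na(data$ic50_um)
  if (any(fill)) {
    data$pic50[fill] <- to_pic50(data$ic50_um[fill], data$id[fill])
  }
  fill2 <- is.na(data$ic50_um) & !is.na(data$pic50)
  data$ic50_um[fill2] <- pic50_to_ic50(data$pic50[fill2])
  both <- !is.na(data$ic50_um) & !is.na(data$pic50)
  off <- both & abs(data$pic50 + log10(data$ic50_um)) > 1e-9
  if (any(off)) {
    abort(paste0("ic50_um and pic50 disagree for: ",
                 paste(data$id[off], collapse = ", ")))
  }
  if (require_activity) {
    need <- data$role %in% c("train", "test")
    miss <- need & is.na(data$pic50)
    if (any(miss)) {
      abort(paste0("missing activity for train/test record(s): ",
                   paste(data$id[miss], collapse = ", ")))
    }
  }
  data
}

#' Read a compound table
#'
#' Reads a comma-separated compound table with a header naming at least `id`
#' and `smiles`, plus activity as `ic50_um`, `ic50_nm` (converted to
#' micromolar) or `pic50`, an optional `role` column (`train`/`test`/
#' `predict`; defaults to `train`), and an optional `source` tag. The
#' Unicode minus sign is accepted in numeric fields so tables copied from
#' typeset documents parse unchanged. Missing activity is allowed only for
#' `role = "predict"` records.
#'
#' @param path Path to a CSV file.
#' @return A compound tibble with columns `id`, `smiles`, `ic50_um`,
#'   `pic50`, `role` (and `source` if present).
#' @export
read_compound_table <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (nrow(raw) == 0L) abort(paste0("empty compound table: ", path))
  num <- function(x) as.numeric(gsub("−", "-", x))
  if ("ic50_nm" %in% names(raw) && !"ic50_um" %in% names(raw)) {
    raw$ic50_um <- num(raw$ic50_nm) / 1000
    raw$ic50_nm <- NULL
  }
  for (cl in intersect(names(raw), c("ic50_um", "pic50"))) {
    raw[[cl]] <- num(raw[[cl]])
  }
  validate_dataset(raw)
}

#' Write a compound table
#'
#' Writes the standard CSV schema read by [read_compound_table()]. Numeric
#' columns are written with full precision so a write/read round trip
#' reproduces activities exactly.
#'
#' @param data Compound tibble.
#' @param path Output path.
#' @return `data`, invisibly.
#' @export
write_compound_table <- function(data, path) {
  data <- validate_dataset(data, require_activity = FALSE)
  readr::write_csv(data, path, progress = FALSE)
  invisible(data)
}

#' Cross-study IC50 normalization through an anchor compound
#'
#' When a series pools activities from two assays, compounds from the second
#' source are rescaled so that an anchor compound measured in both gives the
#' same IC50: every second-source IC50 is multiplied by
#' (anchor IC50 in source 1) / (anchor IC50 in source 2). On the pIC50 scale
#' this is an additive shift. Requires a `source` column with exactly two
#' levels and the anchor measured in both; the anchor may appear as
#' duplicated ids such as `"10"` and `"10b"` sharing an `anchor` marker, or
#' via explicit `anchor_ic50` values.
#'
#' @param data Compound tibble with a `source` column.
#' @param anchor_id Id of the anchor compound, present in both sources
#'   (the second-source copy may be suffixed, e.g. `"10"` and `"10.b"`; any
#'   id whose value up to the first `.` equals `anchor_id` matches).
#' @return The tibble with second-source `ic50_um`/`pic50` rescaled; the
#'   two anchor records end up with identical IC50.
#' @export
normalize_cross_study <- function(data, anchor_id) {
  data <- validate_dataset(data, require_activity = FALSE)
  if (!"source" %in% names(data)) {
    abort("normalize_cross_study() needs a 'source' column")
  }
  src <- unique(data$source)
  if (length(src) != 2L) {
    abort("cross-study normalization expects exactly two sources")
  }
  base_id <- sub("\\..*$", "", data$id)
  g1 <- data$source == src[1]
  g2 <- data$source == src[2]
  a1 <- which(g1 & base_id == anchor_id)
  a2 <- which(g2 & base_id == anchor_id)
  if (length(a1) != 1L || length(a2) != 1L) {
    abort(paste0("anchor '", anchor_id,
                 "' must appear exactly once in each source"))
  }
  ratio <- data$ic50_um[a1] / data$ic50_um[a2]
  data$ic50_um[g2] <- data$ic50_um[g2] * ratio
  data$pic50[g2] <- to_pic50(data$ic50_um[g2], data$id[g2])
  data
}

#' Activity range of a role subset
#'
#' @param data Compound tibble.
#' @param role One of `"train"`, `"test"`, `"predict"`.
#' @return One-row tibble with `role`, `min_pic50`, `max_pic50`, `n`.
#' @examples
#' activity_summary(mmp12_reference(), "train") # min 1.6383, max 4, n 26
#' @export
activity_summary <- function(data, role = "train") {
  role <- match.arg(role, .roles)
  data <- as_tibble(data)
  if (!all(c("id", "role") %in% names(data))) {
    abort("need 'id' and 'role' columns")
  }
  # accept either the modelling schema (pic50) or the reference-table
  # schema (actual_pic50)
  col <- intersect(c("pic50", "actual_pic50"), names(data))[1]
  if (is.na(col)) abort("no pIC50 column ('pic50' or 'actual_pic50') found")
  sub <- data[data$role == role & !is.na(data[[col]]), ]
  if (nrow(sub) == 0L) abort(paste0("no '", role, "' records with activity"))
  tibble(role = role,
         min_pic50 = min(sub[[col]]),
         max_pic50 = max(sub[[col]]),
         n = nrow(sub))
}
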