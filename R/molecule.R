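# Molecular graphs. Structures come in as SMILES and are parsed through
# ChemmineR/OpenBabel into a light heavy-atom graph: elements, bonds with
# orders, per-atom attached-hydrogen counts and heavy-atom degrees. All
# downstream fragment work runs on this representation.

#' Construct a molecular graph directly
#'
#' Low-level constructor for the heavy-atom graph used by the hologram
#' machinery. Normally molecules are built from SMILES via
#' [parse_molecules()]; this constructor exists so that graphs with explicit
#' labels (e.g. stereo parities) can be built programmatically.
#'
#' @param elements Character vector of element symbols, one per heavy atom.
#' @param bonds Data frame with integer columns `a1`, `a2` (1-based atom
#'   indices) and `order` (bond order; 1, 2, 3).
#' @param n_h Integer vector of attached-hydrogen counts per atom.
#' @param parity Integer vector of stereo parities per atom (0 = none).
#' @return An object of class `hqsar_mol`.
#' @export
as_hqsar_mol <- function(elements, bonds, n_h = NULL, parity = NULL) {
  n <- length(elements)
  if (n == 0L) abort("molecule has zero heavy atoms")
  bonds <- as.data.frame(bonds)
  if (nrow(bonds) > 0 &&
      !all(c(bonds$a1, bonds$a2) %in% seq_len(n))) {
    abort("bond indices outside atom range")
  }
  adj <- rep(list(integer(0)), n)
  for (i in seq_len(nrow(bonds))) {
    a <- bonds$a1[i]; b <- bonds$a2[i]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  structure(
    list(
      elements = as.character(elements),
      bonds    = bonds,
      n_h      = as.integer(n_h %||% rep(0L, n)),
      parity   = as.integer(parity %||% rep(0L, n)),
      degree   = lengths(adj),
      adj      = adj,
      n        = n
    ),
    class = "hqsar_mol"
  )
}

#' @export
print.hqsar_mol <- function(x, ...) {
  cat("<hqsar_mol> ", x$n, " heavy atoms (",
      paste(x$elements, collapse = ""), "), ",
      nrow(x$bonds), " bonds\n", sep = "")
  invisible(x)
}

# standard valences used to infer implicit hydrogen counts
.valence <- c(C = 4L, N = 3L, O = 2L, S = 2L, P = 3L,
              F = 1L, Cl = 1L, Br = 1L, I = 1L, B = 3L)

.sdf_to_mol <- function(sdf) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  elements <- sub("_.*$", "", rownames(ab))
  n <- length(elements)
  if (n == 0L) abort("molecule has zero heavy atoms")
  bonds <- if (is.null(dim(bb)) || nrow(bb) == 0) {
    data.frame(a1 = integer(0), a2 = integer(0), order = integer(0))
  } else {
    data.frame(a1 = as.integer(bb[, 1]), a2 = as.integer(bb[, 2]),
               order = as.integer(bb[, 3]))
  }
  # charges via ChemmineR's valence bookkeeping; neutral fallback for
  # degenerate (bond-less) molecules
  charge <- tryCatch(
    as.integer(ChemmineR::bonds(sdf, type = "bonds")$charge),
    error = function(e) rep(0L, n)
  )
  if (length(charge) != n) charge <- rep(0L, n)

  # fold explicit hydrogens into the heavy-atom graph
  is_h <- elements == "H"
  n_h <- rep(0L, n)
  if (any(is_h)) {
    for (i in seq_len(nrow(bonds))) {
      a <- bonds$a1[i]; b <- bonds$a2[i]
      if (is_h[a] && !is_h[b]) n_h[b] <- n_h[b] + 1L
      if (is_h[b] && !is_h[a]) n_h[a] <- n_h[a] + 1L
    }
  }
  # implicit hydrogens from standard valence minus bond-order sum
  order_sum <- rep(0L, n)
  for (i in seq_len(nrow(bonds))) {
    order_sum[bonds$a1[i]] <- order_sum[bonds$a1[i]] + bonds$order[i]
    order_sum[bonds$a2[i]] <- order_sum[bonds$a2[i]] + bonds$order[i]
  }
  val <- .valence[elements]
  val[is.na(val)] <- 0L
  n_h <- n_h + pmax(0L, val - order_sum - abs(charge))

  if (any(is_h)) {
    keep <- which(!is_h)
    remap <- match(seq_len(n), keep)
    bonds <- bonds[!is_h[bonds$a1] & !is_h[bonds$a2], , drop = FALSE]
    bonds$a1 <- remap[bonds$a1]; bonds$a2 <- remap[bonds$a2]
    elements <- elements[keep]; n_h <- n_h[keep]
    if (length(elements) == 0L) abort("molecule has zero heavy atoms")
  }
  as_hqsar_mol(elements, bonds, n_h = n_h)
}

#' Parse SMILES strings into molecular graphs
#'
#' Parses each SMILES via OpenBabel (through ChemmineR) and converts the
#' result into the package's heavy-atom graph representation. Implicit
#' hydrogen counts are inferred from standard valences; explicit hydrogens in
#' the input are folded into the attached-H count of their heavy neighbour.
#' Parsed molecules are cached per SMILES string within the session.
#'
#' @param smiles Character vector of SMILES strings; names (typically
#'   compound ids) are used in error messages and on the result.
#' @return A named list of `hqsar_mol` objects, one per input.
#' @export
parse_molecules <- function(smiles) {
  stopifnot(is.character(smiles))
  ids <- names(smiles) %||% as.character(seq_along(smiles))
  ids[ids == ""] <- as.character(seq_along(smiles))[ids == ""]
  if (is.null(the$mol_cache)) the$mol_cache <- new.env(parent = emptyenv())
  out <- vector("list", length(smiles))
  for (i in seq_along(smiles)) {
    smi <- smiles[[i]]
    if (is.na(smi) || !nzchar(smi)) {
      abort(paste0("record '", ids[i], "': missing structure"))
    }
    hit <- the$mol_cache[[smi]]
    if (!is.null(hit)) { out[[i]] <- hit; next }
    mol <- tryCatch({
      sdfset <- suppressWarnings(ChemmineR::smiles2sdf(setNames(smi, "m")))
      .sdf_to_mol(sdfset[[1]])
    }, error = function(e) {
      abort(paste0("record '", ids[i], "': cannot parse structure '",
                   smi, "' (", conditionMessage(e), ")"))
    })
    the$mol_cache[[smi]] <- mol
    out[[i]] <- mol
  }
  names(out) <- ids
  out
}
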