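# Hologram fingerprints: enumerate connected heavy-atom fragments, give each
# an automorphism-invariant canonical key under the configured distinction
# flags, and hash keys into a fixed-length vector of bin counts. Fragment
# enumeration and canonicalisation are independent of the hologram length, so
# they are computed once per molecule and re-binned cheaply per length.

#' Default catalogue of hologram lengths
#'
#' The conventional catalogue of twelve prime hologram lengths searched when
#' building a model.
#' @return Integer vector of lengths.
#' @export
hologram_lengths <- function() {
  c(53L, 59L, 61L, 71L, 83L, 97L, 151L, 199L, 257L, 307L, 353L, 401L)
}

.distinction_flags <- c("atoms", "bonds", "connections", "hydrogens",
                        "chirality", "donor_acceptor")

#' Hologram fingerprint configuration
#'
#' Collects the settings that define a hologram: the candidate bin lengths,
#' the fragment size window (in heavy atoms), and the distinction flags that
#' decide which atom/bond information enters a fragment's identity. The
#' default distinction set (atoms + connections + hydrogens) is the
#' information setting of the MMP-12 case study; the default size window
#' 4--7 is the conventional fragment size for hologram fingerprints.
#'
#' @param lengths Integer vector of candidate hologram lengths (all >= 2).
#' @param frag_min,frag_max Fragment size bounds in heavy atoms.
#' @param distinctions Character vector drawn from `"atoms"`, `"bonds"`,
#'   `"connections"`, `"hydrogens"`, `"chirality"`, `"donor_acceptor"`.
#' @return An object of class `hologram_config`.
#' @examples
#' hologram_config()
#' hologram_config(lengths = 53, frag_min = 2, frag_max = 5)
#' @export
hologram_config <- function(lengths = hologram_lengths(),
                            frag_min = 4L, frag_max = 7L,
                            distinctions = c("atoms", "connections",
                                             "hydrogens")) {
  lengths <- as.integer(lengths)
  frag_min <- as.integer(frag_min)
  frag_max <- as.integer(frag_max)
  distinctions <- match.arg(distinctions, .distinction_flags,
                            several.ok = TRUE)
  if (length(lengths) == 0L) abort("length catalogue is empty")
  if (any(lengths < 2L)) abort("all hologram lengths must be >= 2")
  if (frag_min < 1L || frag_max < frag_min) {
    abort("need 1 <= frag_min <= frag_max")
  }
  if (length(distinctions) == 0L) abort("distinction set must be non-empty")
  structure(
    list(lengths = lengths, frag_min = frag_min, frag_max = frag_max,
         distinctions = distinctions),
    class = "hologram_config"
  )
}

#' @export
print.hologram_config <- function(x, ...) {
  cat("<hologram_config>\n",
      "  lengths:      ", paste(x$lengths, collapse = ", "), "\n",
      "  fragment size:", x$frag_min, "-", x$frag_max, "heavy atoms\n",
      "  distinctions: ", paste(x$distinctions, collapse = " + "), "\n")
  invisible(x)
}

#' Read a hologram configuration from YAML
#'
#' @param path Path to a YAML file with optional keys `lengths`,
#'   `frag_min`, `frag_max`, `distinctions`.
#' @return A [hologram_config()] object.
#' @export
read_hologram_config <- function(path) {
  y <- yaml::read_yaml(path)
  keep <- intersect(names(y), c("lengths", "frag_min", "frag_max",
                                "distinctions"))
  do.call(hologram_config, y[keep])
}

# ---- fragment enumeration (ESU over connected induced subgraphs) ----------

#' Enumerate connected heavy-atom fragments of a molecule
#'
#' Enumerates every connected induced subgraph of the heavy-atom graph whose
#' size lies within the configured window, each atom-index set exactly once
#' (branched and ring subgraphs included). Uses the ESU scheme: each
#' subgraph is grown from its lowest-index atom with an exclusive extension
#' set, which guarantees single enumeration without an explicit
#' seen-set.
#'
#' @param mol An `hqsar_mol` (see [parse_molecules()]).
#' @param config A [hologram_config()].
#' @return A list of integer vectors, each a sorted set of atom indices.
#' @examples
#' mol <- parse_molecules(c(propane = "CCC"))[[1]]
#' enumerate_fragments(mol, hologram_config(frag_min = 1, frag_max = 3))
#' @export
enumerate_fragments <- function(mol, config = hologram_config()) {
  stopifnot(inherits(mol, "hqsar_mol"))
  if (mol$n == 0L) abort("molecule has zero heavy atoms")
  kmin <- config$frag_min
  kmax <- min(config$frag_max, mol$n)
  if (kmin > mol$n) return(list())
  adj <- mol$adj
  out <- vector("list", 64L)
  cnt <- 0L
  emit <- function(sub) {
    cnt <<- cnt + 1L
    if (cnt > length(out)) length(out) <<- 2L * length(out)
    out[[cnt]] <<- sort.int(sub)
  }
  extend <- function(sub, ext, v) {
    if (length(sub) >= kmin) emit(sub)
    if (length(sub) == kmax) return(invisible(NULL))
    nbr_sub <- unique(unlist(adj[sub], use.names = FALSE))
    while (length(ext) > 0L) {
      w <- ext[1L]
      ext <- ext[-1L]
      nb <- adj[[w]]
      excl <- nb[nb > v & !(nb %in% sub) & !(nb %in% nbr_sub)]
      ext2 <- unique(c(ext, excl))
      ext2 <- ext2[ext2 != w]
      extend(c(sub, w), ext2, v)
    }
  }
  for (v in seq_len(mol$n)) {
    nb <- adj[[v]]
    extend(v, nb[nb > v], v)
  }
  length(out) <- cnt
  out
}

# ---- canonical fragment keys ----------------------------------------------

.atom_labels <- function(mol, distinctions) {
  n <- mol$n
  parts <- character(n)
  if ("atoms" %in% distinctions) parts <- mol$elements
  if ("connections" %in% distinctions) {
    parts <- paste0(parts, ";d", mol$degree)
  }
  if ("hydrogens" %in% distinctions) {
    parts <- paste0(parts, ";h", mol$n_h)
  }
  if ("chirality" %in% distinctions) {
    parts <- paste0(parts, ";s", mol$parity)
  }
  if ("donor_acceptor" %in% distinctions) {
    no <- mol$elements %in% c("N", "O")
    don <- no & mol$n_h >= 1L
    acc <- no # neutral N/O carry a lone pair
    parts <- paste0(parts, ";", ifelse(don & acc, "DA",
                               ifelse(acc, "A", "")))
  }
  parts
}

# all permutations of a small integer vector
.perms <- function(v) {
  n <- length(v)
  if (n == 1L) return(list(v))
  out <- list()
  for (i in seq_len(n)) {
    for (p in .perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
  }
  out
}

#' Canonical key of a fragment
#'
#' Builds an automorphism-invariant string identifying a fragment: the
#' labelled induced subgraph on `atoms`, with per-atom labels determined by
#' the distinction flags (element if `atoms`; heavy-atom degree in the
#' parent molecule if `connections`; attached-H count if `hydrogens`; stereo
#' parity if `chirality`; donor/acceptor class if `donor_acceptor`) and
#' per-edge labels carrying bond order if `bonds`. Canonicalisation uses
#' Weisfeiler-Lehman colour refinement followed by exhaustive ordering
#' within residual colour classes, taking the lexicographically smallest
#' encoding, so any two isomorphic labelled fragments map to the same key.
#'
#' @param mol An `hqsar_mol`.
#' @param atoms Integer vector of atom indices forming a connected induced
#'   subgraph of `mol`.
#' @param distinctions Character vector of distinction flags.
#' @return A single string.
#' @export
fragment_key <- function(mol, atoms,
                         distinctions = c("atoms", "connections",
                                          "hydrogens")) {
  stopifnot(inherits(mol, "hqsar_mol"))
  if (!all(atoms %in% seq_len(mol$n))) abort("fragment atoms not in molecule")
  labels <- .atom_labels(mol, distinctions)[atoms]
  k <- length(atoms)
  # sub-adjacency with edge labels
  amat <- matrix(0L, k, k)
  pos <- match(seq_len(mol$n), atoms)
  b <- mol$bonds
  inside <- !is.na(pos[b$a1]) & !is.na(pos[b$a2])
  use_bonds <- "bonds" %in% distinctions
  for (i in which(inside)) {
    x <- pos[b$a1[i]]; y <- pos[b$a2[i]]
    lab <- if (use_bonds) b$order[i] else 1L
    amat[x, y] <- lab
    amat[y, x] <- lab
  }
  # Weisfeiler-Lehman refinement
  colors <- match(labels, sort(unique(labels)))
  repeat {
    sig <- vapply(seq_len(k), function(i) {
      nb <- which(amat[i, ] > 0L)
      paste0(colors[i], "(", labels[i], ")|",
             paste(sort(paste0(amat[i, nb], ":", colors[nb])),
                   collapse = ","))
    }, character(1))
    new <- match(sig, sort(unique(sig)))
    if (identical(new, colors)) break
    colors <- new
  }
  # order atoms: colour classes in signature order, exhaustive within class
  sig <- vapply(seq_len(k), function(i) {
    paste0(formatC(colors[i], width = 3, flag = "0"), "|", labels[i])
  }, character(1))
  classes <- split(seq_len(k), sig)
  class_perms <- lapply(classes, .perms)
  n_orders <- prod(lengths(class_perms))
  encode <- function(ord) {
    lab_part <- paste(labels[ord], collapse = "|")
    inv <- integer(k); inv[ord] <- seq_len(k)
    edges <- character(0)
    for (x in seq_len(k - 1L)) for (y in seq(x + 1L, k)) {
      o <- amat[ord[x], ord[y]]
      if (o > 0L) edges <- c(edges, paste0(x, "-", y, ":", o))
    }
    paste0(lab_part, "#", paste(sort(edges), collapse = ","))
  }
  if (k == 1L) return(encode(1L))
  best <- NULL
  idx <- rep(1L, length(class_perms))
  sizes <- lengths(class_perms)
  for (r in seq_len(n_orders)) {
    ord <- unlist(Map(function(ps, j) ps[[j]], class_perms, idx),
                  use.names = FALSE)
    enc <- encode(ord)
    if (is.null(best) || enc < best) best <- enc
    # advance mixed-radix counter
    for (d in seq_along(idx)) {
      idx[d] <- idx[d] + 1L
      if (idx[d] <= sizes[d]) break
      idx[d] <- 1L
    }
  }
  best
}

# canonical keys for every fragment occurrence of one molecule, cached
.molecule_keys <- function(mol, config, cache_id = NULL) {
  if (!is.null(cache_id)) {
    if (is.null(the$frag_cache)) the$frag_cache <- new.env(parent = emptyenv())
    ck <- paste(cache_id, config$frag_min, config$frag_max,
                paste(config$distinctions, collapse = "+"), sep = "\r")
    hit <- the$frag_cache[[ck]]
    if (!is.null(hit)) return(hit)
  }
  frags <- enumerate_fragments(mol, config)
  keys <- vapply(frags, fragment_key, character(1),
                 mol = mol, distinctions = config$distinctions)
  if (!is.null(cache_id)) the$frag_cache[[ck]] <- keys
  keys
}

# ---- hologram construction -------------------------------------------------

.bin_of_key <- function(keys, L) {
  uk <- unique(keys)
  bins <- (crc32(uk) %% L) + 1
  as.integer(bins)[match(keys, uk)]
}

#' Build a hologram from fragment keys
#'
#' Hashes each fragment occurrence into one of `L` bins using the CRC-32 of
#' its canonical key modulo `L`, and counts occurrences per bin. The sum of
#' the counts always equals the number of fragment occurrences; hashing only
#' redistributes them.
#'
#' @param keys Character vector of canonical fragment keys, one per
#'   occurrence (see [fragment_key()]).
#' @param L Hologram length (integer >= 2).
#' @return Integer vector of length `L` of bin counts, with attribute
#'   `total` equal to `length(keys)`.
#' @export
build_hologram <- function(keys, L) {
  L <- as.integer(L)
  if (is.na(L) || L < 2L) abort("hologram length must be >= 2")
  counts <- integer(L)
  if (length(keys) > 0) {
    tab <- tabulate(.bin_of_key(keys, L), nbins = L)
    counts <- as.integer(tab)
  }
  attr(counts, "total") <- length(keys)
  counts
}

#' Fragment keys for every compound in a dataset
#'
#' Parses each structure and returns the canonical fragment keys of all its
#' fragment occurrences. This is the length-independent half of
#' featurization; [hologram_matrix()] bins the keys at a given length.
#'
#' @param data Compound tibble with `id` and `smiles` columns.
#' @param config A [hologram_config()].
#' @return Named list (by compound id) of character vectors of keys.
#' @export
dataset_fragments <- function(data, config = hologram_config()) {
  data <- validate_dataset(data, require_activity = FALSE)
  if (!"smiles" %in% names(data) || anyNA(data$smiles)) {
    abort("featurization needs a complete 'smiles' column")
  }
  mols <- parse_molecules(setNames(data$smiles, data$id))
  lapply(seq_along(mols), function(i) {
    .molecule_keys(mols[[i]], config, cache_id = data$smiles[i])
  }) |> setNames(data$id)
}

#' Bin per-compound fragment keys into a hologram matrix
#'
#' @param frag_keys Named list of key vectors from [dataset_fragments()].
#' @param L Hologram length.
#' @return Integer matrix, one row per compound (rownames = ids), `L`
#'   columns.
#' @export
hologram_matrix <- function(frag_keys, L) {
  L <- as.integer(L)
  if (is.na(L) || L < 2L) abort("hologram length must be >= 2")
  n <- length(frag_keys)
  X <- matrix(0L, nrow = n, ncol = L,
              dimnames = list(names(frag_keys), paste0("bin", seq_len(L))))
  for (i in seq_len(n)) X[i, ] <- build_hologram(frag_keys[[i]], L)
  X
}

#' Featurize a compound table into a hologram matrix
#'
#' Convenience wrapper: enumerate + canonicalise fragments for every
#' compound ([dataset_fragments()]) and bin them at length `L`
#' ([hologram_matrix()]). Row order follows the input table.
#'
#' @inheritParams dataset_fragments
#' @param L Hologram length.
#' @return Integer matrix `n_compounds x L` with compound ids as rownames.
#' @export
featurize_dataset <- function(data, config = hologram_config(),
                              L = config$lengths[1]) {
  hologram_matrix(dataset_fragments(data, config), L)
}
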