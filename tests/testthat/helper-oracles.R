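# Independent oracles and shared fixtures. Each oracle is written from the
# mathematical definition, not from the package's code path.

# all connected induced subgraphs with sizes in [kmin, kmax], by power-set
# enumeration plus a BFS connectivity check (molecules <= ~10 heavy atoms)
brute_force_subgraphs <- function(mol, kmin, kmax) {
  n <- mol$n
  adj <- mol$adj
  connected <- function(s) {
    seen <- s[1]; queue <- s[1]
    while (length(queue) > 0) {
      w <- queue[1]; queue <- queue[-1]
      nb <- intersect(adj[[w]], s)
      new <- setdiff(nb, seen)
      seen <- c(seen, new); queue <- c(queue, new)
    }
    length(seen) == length(s)
  }
  out <- list()
  for (k in seq(kmin, min(kmax, n))) {
    for (s in utils::combn(n, k, simplify = FALSE)) {
      if (connected(s)) out[[length(out) + 1L]] <- s
    }
  }
  out
}

canon_sets <- function(sets) sort(vapply(sets, paste, "", collapse = ","))

# PLS1 oracle via the Krylov-subspace identity: the c-component PLS1 fit
# equals least squares of centred y on the Krylov basis
# K = [s, As, ..., A^{c-1} s], A = Xc'Xc, s = Xc'y.
krylov_pls <- function(X, y, ncomp) {
  X <- as.matrix(X)
  xm <- colMeans(X); ym <- mean(y)
  Xc <- sweep(X, 2, xm); yc <- y - ym
  A <- crossprod(Xc)
  s <- drop(crossprod(Xc, yc))
  K <- matrix(0, ncol(X), ncomp)
  v <- s
  for (h in seq_len(ncomp)) {
    K[, h] <- v / sqrt(sum(v^2)) # normalised for conditioning
    v <- drop(A %*% K[, h])
  }
  gamma <- qr.solve(crossprod(K, A %*% K), drop(crossprod(K, s)))
  beta <- drop(K %*% gamma)
  list(coefficients = beta,
       intercept = ym - sum(xm * beta),
       fitted = drop(X %*% beta) + ym - sum(xm * beta))
}

# small-molecule corpus for enumeration oracles (all <= 8 heavy atoms)
small_corpus <- function() {
  c(ethane = "CC", propane = "CCC", ethanol = "CCO", isobutane = "CC(C)C",
    cyclopropane = "C1CC1", cyclobutane = "C1CCC1", benzene = "c1ccccc1",
    pyridine = "c1ccncc1", furan = "c1ccoc1", butanol = "CCCCO",
    methylcyclopropane = "CC1CC1", alanine = "CC(N)C(=O)O")
}

# Conditions of the parameter-recovery experiment: noise-free series with a
# short fragment window, so the fragment population (about 50 distinct
# keys) hashes near-injectively into the length catalogue and the
# fragment-additive truth is identifiable. Built once per session.
recovery_config <- function() hologram_config(frag_min = 1, frag_max = 2)

recovery_series <- function() {
  if (is.null(.test_cache$series)) {
    .test_cache$series <- generate_series(series_spec(
      seed = 1, noise_sd = 0, config = recovery_config(), min_support = 4
    ))
  }
  .test_cache$series
}

recovery_model <- function() {
  if (is.null(.test_cache$model)) {
    .test_cache$model <- hqsar_train(recovery_series(),
                                     config = recovery_config(),
                                     max_components = 12)
  }
  .test_cache$model
}

.test_cache <- new.env(parent = emptyenv())
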