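test_that("CRC-32 matches the published check values", {
  expect_equal(crc32("123456789"), 3421780262)
  expect_equal(crc32(""), 0)
  expect_equal(crc32(c("a", "abc")), c(3904355907, 891568578))
})

test_that("fragment counts on hand-enumerable molecules are exact", {
  mols <- parse_molecules(c(ethane = "CC", propane = "CCC",
                            benzene = "c1ccccc1"))
  cfg12 <- hologram_config(frag_min = 1, frag_max = 2)
  fr_eth <- enumerate_fragments(mols$ethane, cfg12)
  expect_length(fr_eth, 3L) # two atoms + one bond
  keys_eth <- vapply(fr_eth, fragment_key, "", mol = mols$ethane,
                     distinctions = "atoms")
  expect_length(unique(keys_eth), 2L)

  cfg13 <- hologram_config(frag_min = 1, frag_max = 3)
  fr_pro <- enumerate_fragments(mols$propane, cfg13)
  expect_length(fr_pro, 6L) # 3 + 2 + 1
  keys_pro <- vapply(fr_pro, fragment_key, "", mol = mols$propane,
                     distinctions = "atoms")
  expect_length(unique(keys_pro), 3L)

  cfg16 <- hologram_config(frag_min = 1, frag_max = 6)
  expect_length(enumerate_fragments(mols$benzene, cfg16), 31L)
})

test_that("enumeration agrees exactly with brute force over the corpus", {
  mols <- parse_molecules(small_corpus())
  set.seed(17)
  for (mol in mols) {
    kmin <- sample(1:3, 1)
    kmax <- if (kmin >= mol$n) mol$n else kmin + sample(0:(mol$n - kmin), 1)
    cfg <- hologram_config(frag_min = kmin, frag_max = kmax)
    got <- canon_sets(enumerate_fragments(mol, cfg))
    want <- canon_sets(brute_force_subgraphs(mol, kmin, kmax))
    expect_identical(got, want)
    expect_false(any(duplicated(got)))
  }
})

test_that("distinction flags control what enters a fragment's identity", {
  mols <- parse_molecules(c(pro = "CCC", eth = "CC", etoh = "CCO"))
  pro <- mols$pro
  # symmetric atoms share a key
  expect_identical(fragment_key(pro, 1L, "atoms"),
                   fragment_key(pro, 3L, "atoms"))
  # terminal vs central carbon split by the connections flag
  expect_identical(fragment_key(pro, 1L, "atoms"),
                   fragment_key(pro, 2L, "atoms"))
  expect_false(identical(fragment_key(pro, 1L, c("atoms", "connections")),
                         fragment_key(pro, 2L, c("atoms", "connections"))))
  # the C-C fragment of ethanol differs from ethane's under the
  # hydrogens flag (one carbon lost an H to the hydroxyl substituent)
  key_eth <- fragment_key(mols$eth, c(1L, 2L), c("atoms", "hydrogens"))
  key_etoh <- fragment_key(mols$etoh, c(1L, 2L), c("atoms", "hydrogens"))
  expect_false(identical(key_eth, key_etoh))
  expect_identical(fragment_key(mols$eth, c(1L, 2L), "atoms"),
                   fragment_key(mols$etoh, c(1L, 2L), "atoms"))
  # bond orders enter only under the bonds flag
  ethene <- parse_molecules(c(x = "C=C"))[[1]]
  expect_identical(fragment_key(mols$eth, c(1L, 2L), "atoms"),
                   fragment_key(ethene, c(1L, 2L), "atoms"))
  expect_false(identical(fragment_key(mols$eth, c(1L, 2L),
                                      c("atoms", "bonds")),
                         fragment_key(ethene, c(1L, 2L),
                                      c("atoms", "bonds"))))
})

test_that("chirality and donor/acceptor labels are honoured when enabled", {
  bonds <- data.frame(a1 = 1L, a2 = 2L, order = 1L)
  m1 <- as_hqsar_mol(c("C", "C"), bonds, n_h = c(1L, 1L),
                     parity = c(1L, 0L))
  m2 <- as_hqsar_mol(c("C", "C"), bonds, n_h = c(1L, 1L),
                     parity = c(2L, 0L))
  expect_identical(fragment_key(m1, 1:2, "atoms"),
                   fragment_key(m2, 1:2, "atoms"))
  expect_false(identical(fragment_key(m1, 1:2, c("atoms", "chirality")),
                         fragment_key(m2, 1:2, c("atoms", "chirality"))))
  # hydroxyl O is donor+acceptor, ether O acceptor only
  etoh <- parse_molecules(c(a = "CCO"))[[1]]
  dme <- parse_molecules(c(b = "COC"))[[1]]
  k1 <- fragment_key(etoh, which(etoh$elements == "O"),
                     c("atoms", "donor_acceptor"))
  k2 <- fragment_key(dme, which(dme$elements == "O"),
                     c("atoms", "donor_acceptor"))
  expect_false(identical(k1, k2))
})

test_that("holograms are invariant to atom renumbering of the input", {
  variants <- list(
    ethanol = c("CCO", "OCC", "C(O)C"),
    toluene = c("Cc1ccccc1", "c1ccccc1C", "c1ccc(C)cc1")
  )
  cfg <- hologram_config(frag_min = 1, frag_max = 4)
  for (v in variants) {
    holos <- lapply(seq_along(v), function(i) {
      mol <- parse_molecules(setNames(v[i], paste0("v", i)))[[1]]
      fr <- enumerate_fragments(mol, cfg)
      keys <- vapply(fr, fragment_key, "", mol = mol,
                     distinctions = cfg$distinctions)
      build_hologram(keys, 97L)
    })
    for (i in 2:length(holos)) expect_identical(holos[[i]], holos[[1]])
  }
})

test_that("hologram counts conserve the number of fragment occurrences", {
  mols <- parse_molecules(small_corpus())
  cfg <- hologram_config(frag_min = 1, frag_max = 4)
  for (mol in mols) {
    fr <- enumerate_fragments(mol, cfg)
    keys <- vapply(fr, fragment_key, "", mol = mol,
                   distinctions = cfg$distinctions)
    for (L in c(2L, 53L, 199L, 401L)) {
      h <- build_hologram(keys, L)
      expect_identical(sum(h), length(fr))
      expect_identical(attr(h, "total"), length(fr))
    }
    # determinism
    expect_identical(build_hologram(keys, 199L), build_hologram(keys, 199L))
  }
  expect_error(build_hologram(character(0), 1L), ">= 2")
  h0 <- build_hologram(character(0), 53L)
  expect_identical(sum(h0), 0L)
})

test_that("longer holograms spread a large fragment population over more bins", {
  # a fragment population much larger than the shortest length, so the
  # statistical occupancy trend dominates per-length fluctuations
  cfg <- hologram_config(frag_min = 4, frag_max = 7)
  mol <- parse_molecules(c(x = "OC(=O)c1ccc2c(c1)oc1ccc(CC(C)C)cc12"))[[1]]
  fr <- enumerate_fragments(mol, cfg)
  keys <- vapply(fr, fragment_key, "", mol = mol,
                 distinctions = cfg$distinctions)
  expect_gt(length(unique(keys)), 150)
  occ <- vapply(hologram_lengths(), function(L) {
    sum(build_hologram(keys, L) > 0)
  }, numeric(1))
  # every length beyond the shortest holds at least as many occupied bins
  expect_true(all(occ >= occ[1]))
  # and the longest spreads the population far wider than the shortest
  expect_gt(occ[length(occ)], 2 * occ[1])
})

test_that("featurization preserves row order and congeneric structure", {
  d <- tibble::tibble(id = c("a", "b", "c"),
                      smiles = c("CCO", "CCO", "CCCO"),
                      role = "predict")
  cfg <- hologram_config(frag_min = 1, frag_max = 3)
  X <- featurize_dataset(d, cfg, L = 61)
  expect_identical(rownames(X), d$id)
  expect_identical(X["a", ], X["b", ]) # duplicate SMILES, identical rows
  # rows of a congeneric pair differ only in bins hit by differing keys
  fk <- dataset_fragments(d, cfg)
  diff_keys <- c(setdiff(unique(fk$a), unique(fk$c)),
                 setdiff(unique(fk$c), unique(fk$a)),
                 # shared keys with different occurrence counts also differ
                 intersect(unique(fk$a), unique(fk$c))[
                   vapply(intersect(unique(fk$a), unique(fk$c)), function(k) {
                     sum(fk$a == k) != sum(fk$c == k)
                   }, logical(1))])
  allowed_bins <- unique(crc32(diff_keys) %% 61 + 1)
  expect_true(all(which(X["a", ] != X["c", ]) %in% allowed_bins))
  # n = 0 gives an empty matrix
  X0 <- hologram_matrix(setNames(list(), character(0)), 53)
  expect_identical(dim(X0), c(0L, 53L))
  # unparsable structure is reported by id
  expect_error(
    featurize_dataset(tibble::tibble(id = "zz", smiles = "not-a-smiles",
                                     role = "predict"), cfg, 53),
    "zz"
  )
})

test_that("configuration objects validate their invariants", {
  expect_error(hologram_config(lengths = integer(0)), "empty")
  expect_error(hologram_config(lengths = 1), ">= 2")
  expect_error(hologram_config(frag_min = 5, frag_max = 3), "frag_min")
  expect_error(hologram_config(distinctions = "colour"), "arg")
  cfg <- hologram_config()
  expect_identical(cfg$lengths, hologram_lengths())
  expect_identical(cfg$distinctions, c("atoms", "connections", "hydrogens"))
  # YAML round trip
  path <- withr::local_tempfile(fileext = ".yml")
  yaml::write_yaml(list(lengths = c(53, 97), frag_min = 2, frag_max = 5,
                        distinctions = c("atoms", "bonds")), path)
  cfg2 <- read_hologram_config(path)
  expect_identical(cfg2$lengths, c(53L, 97L))
  expect_identical(cfg2$distinctions, c("atoms", "bonds"))
})
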