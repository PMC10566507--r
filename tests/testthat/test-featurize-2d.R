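test_that("Morgan fingerprints are deterministic and well-behaved", {
  f1 <- morgan_fingerprint("CC(=O)O")
  f2 <- morgan_fingerprint("OC(=O)C")  # same molecule, different spelling
  expect_identical(f1, f2)
  expect_length(f1, 2048)
  expect_true(all(f1 %in% c(0L, 1L)))
  expect_equal(tanimoto(f1, f1), 1.0)
  # methane: a single heavy atom has very few circular environments
  fm <- morgan_fingerprint("C", radius = 2, n_bits = 2048)
  expect_gte(sum(fm), 1)
  expect_lt(sum(fm), 10)
  expect_error(morgan_fingerprint("C", n_bits = 0), "n_bits")
})

test_that("fingerprints separate molecules and respect radius", {
  mols <- unique(canonicalize(random_fragment_smiles(20, seed = 3)))
  fps <- vapply(mols, morgan_fingerprint, integer(2048))
  sims <- crossprod(fps)
  # distinct molecules should not collide into identical fingerprints
  for (i in seq_along(mols)) {
    for (j in seq_len(i - 1)) {
      expect_false(all(fps[, i] == fps[, j]),
                   info = paste(mols[i], "vs", mols[j]))
    }
  }
})

test_that("the 2D battery has a broad fixed schema with sane anchor values", {
  b <- battery_2d("O")    # water
  expect_gte(length(b), 200)
  expect_equal(b[["mol_weight"]], 18.015, tolerance = 1e-3)
  expect_identical(names(b), names(battery_2d("c1ccccc1")))
  benzene <- battery_2d("c1ccccc1")
  expect_equal(benzene[["n_heavy"]], 6)
  expect_equal(benzene[["n_rings"]], 1)
  expect_equal(benzene[["n_aromatic_C"]], 6)
  biphenyl <- battery_2d("c1ccc(-c2ccccc2)cc1")
  expect_equal(biphenyl[["n_rings"]], 2)
  acetic <- battery_2d("CC(=O)O")
  expect_equal(acetic[["fg_carboxyl"]], 1)
  expect_equal(acetic[["n_HBD"]], 1)
})

test_that("assembly concatenates blocks with provenance and exact widths", {
  ds <- subset_dataset(small_synthetic()$dataset, 1:12)
  fb <- assemble_reaction_features(ds, "fingerprint", roles = c("acid", "amine"))
  expect_equal(ncol(fb$matrix), 4096)
  expect_true(all(startsWith(fb$feature_names[1:2048], "acid_fp")))
  with_ctx <- assemble_reaction_features(ds, c("fingerprint", "context"),
                                         roles = c("acid", "amine"))
  expect_equal(ncol(with_ctx$matrix),
               4096 + ds$context_vocab$dimension)
  expect_error(assemble_reaction_features(ds, "fingerprint", roles = character(0)),
               "role")
  expect_error(assemble_reaction_features(ds, "nope"), "unknown feature block")
})

test_that("variance filtering removes constants and missing values, idempotently", {
  m <- cbind(const = rep(1, 10), ok = rnorm(10), missing = c(NA, rnorm(9)),
             tiny = rep(c(1, 1 + 1e-9), 5))
  blk <- feature_block("test", m)
  filtered <- variance_filter(blk, threshold = 1e-6)
  expect_identical(colnames(filtered$matrix), "ok")
  expect_identical(variance_filter(filtered, 1e-6)$matrix, filtered$matrix)
  # threshold 0: only the missing-value column goes
  f0 <- variance_filter(blk, threshold = 0)
  expect_identical(colnames(f0$matrix), c("const", "ok", "tiny"))
  # retained variances really are above threshold (independent two-pass check)
  two_pass_var <- apply(filtered$matrix, 2, function(x) {
    mu <- sum(x) / length(x); sum((x - mu)^2) / (length(x) - 1)
  })
  expect_true(all(two_pass_var >= 1e-6))
  expect_error(variance_filter(feature_block("z", m[, 3, drop = FALSE]), 0),
               "every column")
})

test_that("RFE keeps the informative support and hits exact targets", {
  set.seed(11)
  X <- matrix(rnorm(150 * 50), 150, 50,
              dimnames = list(NULL, paste0("f", 1:50)))
  y <- 3 * X[, 5] - 2 * X[, 17] + 1.5 * X[, 42] + rnorm(150, 0, 0.1)
  hits <- 0
  for (s in 1:10) {
    blk <- feature_block("x", X)
    sel <- rfe_select(list(x = blk), y,
                      selection_plan(c(x = 3L), seed = s))
    expect_equal(ncol(sel$matrix), 3)
    if (setequal(colnames(sel$matrix), c("f5", "f17", "f42"))) hits <- hits + 1
  }
  expect_gte(hits, 9)  # >= 90% of seeded runs recover the support
  # target equal to width leaves the block unchanged
  same <- rfe_select(list(x = feature_block("x", X)), y,
                     selection_plan(c(x = 50L)))
  expect_identical(colnames(same$matrix), colnames(X))
  expect_error(rfe_select(list(x = feature_block("x", X)), y,
                          selection_plan(c(x = 51L))), "exceeds")
})

test_that("merged RFE widths add up across blocks", {
  set.seed(2)
  blocks <- list(
    a = feature_block("a", matrix(rnorm(100 * 20), 100, 20)),
    b = feature_block("b", matrix(rnorm(100 * 15), 100, 15)))
  y <- rnorm(100)
  merged <- rfe_select(blocks, y, selection_plan(c(a = 7L, b = 4L)))
  expect_equal(ncol(merged$matrix), 11)
})
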