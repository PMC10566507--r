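test_that("fragment libraries are seeded, valid and class-complete", {
  cfg <- generator_config(seed = 5)
  lib1 <- build_fragment_library(cfg)
  lib2 <- build_fragment_library(cfg)
  expect_identical(lib1, lib2)
  for (a in lib1$acids) {
    g <- amideml:::parse_smiles(a)
    expect_length(amideml:::find_carboxyl_groups(g), 1)
  }
  cls <- vapply(lib1$amines, classify_amine, character(1))
  expect_identical(unname(cls), lib1$amine_class)
  expect_setequal(unique(cls),
                  c("primary_aliphatic", "primary_aromatic", "secondary"))
})

test_that("latent yield is deterministic and ignores zero-coefficient edits", {
  coef <- yield_coefficients(context_effects = c("solvent:dmf" = 2),
                             size = 0)
  ctx <- reaction_context(solvents = "dmf")
  y1 <- latent_yield("OC(=O)CCCc1ccc(OCc2ccccc2)cc1", "NCC", ctx, coef)
  y2 <- latent_yield("OC(=O)CCCc1ccc(OCc2ccccc2)cc1", "NCC", ctx, coef)
  expect_identical(y1, y2)
  # remote methyl edit only touches the (zeroed) size term
  edited <- "OC(=O)CCCc1ccc(OCc2ccc(C)cc2)cc1"
  expect_equal(latent_yield(edited, "NCC", ctx, coef), y1)
  expect_true(y1 > 0 && y1 < 100)
})

test_that("generation is deterministic and validator-closed", {
  gen <- small_synthetic()
  regen <- generate_dataset(generator_config(
    n_reactions = 200L, n_planted_cliffs = 10L, n_planted_uncertain = 5L,
    uncertain_group_size = 3L, seed = 42L))
  expect_identical(dataset_to_frame(gen$dataset), dataset_to_frame(regen$dataset))
  bad <- vapply(gen$dataset$records, function(r) length(validate_record(r)) > 0,
                logical(1))
  expect_identical(sum(bad), 0L)
})

test_that("planted structure satisfies its construction postconditions", {
  gen <- small_synthetic()
  ds <- gen$dataset
  ids <- vapply(ds$records, function(r) r$reaction_id, character(1))
  ys <- yields(ds)
  feats <- cliff_features(ds)
  for (k in seq_len(nrow(gen$truth$cliff_pairs))) {
    i <- match(gen$truth$cliff_pairs$id_a[k], ids)
    j <- match(gen$truth$cliff_pairs$id_b[k], ids)
    expect_gt(pairwise_similarity(feats, i, j), 0.9)
    expect_gte(abs(ys[i] - ys[j]), 30)
    expect_false(reaction_signature(ds$records[[i]]) ==
                   reaction_signature(ds$records[[j]]))
  }
  for (grp in gen$truth$uncertain_groups) {
    ix <- match(grp, ids)
    sigs <- vapply(ds$records[ix], reaction_signature, character(1))
    expect_length(unique(sigs), 1)
    expect_gt(max(ys[ix]) - min(ys[ix]), 0)
  }
})

test_that("the yield distribution is high-yield-skewed with the target mean", {
  gen <- fixture("mean_check", function() {
    generate_dataset(generator_config(n_reactions = 5000L, seed = 9L))
  })
  lat <- unname(gen$truth$latent_yield)
  expect_lt(abs(mean(lat) - 64.1), 2)
  expect_gt(mean(yields(gen$dataset) > 50), 0.6)
})

test_that("the yield-energy correlation lands in the calibrated band", {
  # two seeds at moderate n; the acceptance suite covers the full design
  for (s in c(3L, 8L)) {
    gen <- generate_dataset(generator_config(n_reactions = 2000L, seed = s,
                                             n_planted_cliffs = 50L))
    prov_e <- attr(oracle_qm_provider(gen$truth), "energy_fun")
    e_water <- prov_e("O")
    de <- vapply(gen$dataset$records, function(r) {
      delta_e_rxn(prov_e(r$product$smiles), e_water, prov_e(r$acid$smiles),
                  prov_e(r$amine$smiles))
    }, numeric(1))
    rho <- cor(yields(gen$dataset), de)
    expect_gt(rho, -0.2)
    expect_lt(rho, -0.05)
  }
})

test_that("infeasible planting configurations fail loudly", {
  expect_error(generator_config(n_reactions = 10L, n_planted_cliffs = 4L,
                                n_planted_uncertain = 2L,
                                uncertain_group_size = 3L),
               "planted structure")
  expect_error(generator_config(cliff_gap = 0), "cliff_gap")
})
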