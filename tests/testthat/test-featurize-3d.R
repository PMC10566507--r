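test_that("conformer embedding is seeded, connected and chemically sane", {
  c1 <- embed_conformer("C", seed = 1)
  c2 <- embed_conformer("C", seed = 1)
  expect_identical(c1$coords, c2$coords)
  d <- sqrt(rowSums((c1$coords[c1$species == "H", ] -
                       matrix(c1$coords[c1$species == "C", ], 4, 3,
                              byrow = TRUE))^2))
  expect_true(all(d >= 1.0 & d <= 1.2))
  expect_error(embed_conformer("C.C", seed = 1), "disconnected")
})

test_that("AEVs vanish without neighbors and match the radial closed form", {
  lone <- conformer3d("C", matrix(0, 1, 3))
  expect_true(all(compute_aev(lone) == 0))
  far <- conformer3d(c("C", "C"), rbind(c(0, 0, 0), c(9, 0, 0)))
  expect_true(all(compute_aev(far) == 0))
  # H-H at 1.0 A, single shell Rs = 1.0, eta = 16, Rc = 5.2
  hh <- conformer3d(c("H", "H"), rbind(c(0, 0, 0), c(1, 0, 0)))
  p <- aev_params(radial_shells = 1)
  p$radial_rs <- 1.0
  av <- compute_aev(hh, p)
  expected <- exp(0) * (0.5 * cos(pi * 1.0 / 5.2) + 0.5)
  expect_equal(unname(av[1, "rad_H_1"]), expected, tolerance = 1e-12)
  expect_equal(unname(av[2, "rad_H_1"]), expected, tolerance = 1e-12)
  expect_error(compute_aev(conformer3d("Br", matrix(0, 1, 3))), "channel")
})

test_that("AEVs are invariant to rigid motion and identical-atom permutation", {
  mols <- c("CCO", "CC(=O)O", "c1ccccc1", "CCN", "CC(C)C")
  for (k in seq_along(mols)) {
    conf <- embed_conformer(mols[k], seed = k)
    base <- compute_aev(conf)
    th <- 0.3 + 0.2 * k; ph <- 0.1 * k
    R1 <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
    R2 <- matrix(c(1, 0, 0, 0, cos(ph), -sin(ph), 0, sin(ph), cos(ph)), 3, 3)
    moved <- conformer3d(conf$species, conf$coords %*% (R1 %*% R2) + 2.5)
    expect_lt(max(abs(compute_aev(moved) - base)), 1e-8)
  }
  # swapping two identical atoms permutes rows but leaves the pooled vector
  conf <- embed_conformer("CCO", seed = 5)
  hs <- which(conf$species == "H")[1:2]
  perm <- seq_along(conf$species)
  perm[hs] <- rev(hs)
  swapped <- conformer3d(conf$species[perm], conf$coords[perm, ])
  expect_equal(pool_aev(compute_aev(swapped)), pool_aev(compute_aev(conf)),
               tolerance = 1e-10)
})

test_that("sum-pooling is linear and order-free", {
  conf <- embed_conformer("CCO", seed = 2)
  av <- compute_aev(conf)
  expect_equal(pool_aev(av[1, , drop = FALSE]), av[1, ])
  expect_equal(pool_aev(rbind(av, av)), 2 * pool_aev(av))
  expect_equal(pool_aev(av[rev(seq_len(nrow(av))), ]), pool_aev(av))
  expect_error(pool_aev(av[0, , drop = FALSE]), "at least one atom")
})

test_that("buried volume matches the single-sphere closed form and is monotone", {
  single <- conformer3d("C", matrix(0, 1, 3))
  params <- steric_params(probe_radius = 3.5, grid_spacing = 0.1)
  v1 <- buried_volume(single, 1, params)
  expect_equal(v1, 100 * (1.7 / 3.5)^3, tolerance = 2)  # percentage points
  # a remote atom changes nothing
  remote <- conformer3d(c("C", "C"), rbind(c(0, 0, 0), c(40, 0, 0)))
  expect_equal(buried_volume(remote, 1, params), v1)
  # adding occluders inside the probe sphere never decreases the value
  positions <- rbind(c(0, 0, 0), c(2.5, 0, 0), c(0, 2.2, 0), c(-1.8, 0, 1))
  prev <- -Inf
  for (k in 1:4) {
    conf <- conformer3d(rep("C", k), positions[1:k, , drop = FALSE])
    cur <- buried_volume(conf, 1, params)
    expect_gte(cur, prev - 1e-9)
    prev <- cur
  }
  expect_error(steric_params(probe_radius = 1, grid_spacing = 2), "spacing")
})

test_that("buried volume converges as the grid refines", {
  mols <- canonicalize(c("CC(=O)O", "CCN", "c1ccccc1", "CCO", "CC(C)C",
                         "CNC", "CCC", "COC", "CCS", "CCCl"))
  for (k in seq_along(mols)) {
    conf <- embed_conformer(mols[k], seed = k)
    coarse <- buried_volume(conf, 1, steric_params(grid_spacing = 0.2))
    fine <- buried_volume(conf, 1, steric_params(grid_spacing = 0.1))
    expect_lt(abs(coarse - fine), 0.5)
  }
})

test_that("surrogate QM records are deterministic with coverage limits", {
  prov <- heuristic_qm_provider()
  r1 <- qm_features("CC(=O)O", prov)
  r2 <- qm_features("OC(=O)C", prov)
  expect_identical(r1, r2)
  g <- amideml:::parse_smiles("CC(=O)O")
  expect_length(r1$charges, g$n)
  expect_length(r1$fukui_plus, g$n)
  expect_error(qm_features("CCBr", prov), "coverage")
})

test_that("reaction energies and Fukui differences follow their definitions", {
  expect_equal(delta_e_rxn(-100, -76, -120, -55), -1)
  expect_equal(delta_e_rxn(-3, -7, -3, -7), 0)
  expect_equal(delta_e_rxn(-200, -152, -240, -110), 2 * delta_e_rxn(-100, -76, -120, -55))
  prov <- heuristic_qm_provider()
  water <- prov("O")
  acid <- prov(canonicalize("CC(=O)O")); amine <- prov(canonicalize("CN"))
  product <- prov(condense_product("CC(=O)O", "CN")$smiles)
  ctr <- annotate_reaction_centers("CC(=O)O", "CN",
                                   condense_product("CC(=O)O", "CN"))
  vec <- derive_reaction_qm(acid, amine, product, water, ctr)
  expect_equal(vec[["dE_rxn"]],
               delta_e_rxn(product$energy, water$energy, acid$energy,
                           amine$energy))
  expect_equal(vec[["df_rxn"]],
               vec[["f_plus_acid_c"]] - vec[["f_minus_amine_n"]])
  # mixing providers is refused
  fake <- acid; fake$provider <- "other"
  expect_error(derive_reaction_qm(fake, amine, product, water, ctr), "mixed")
})

test_that("yield correlates negatively with the oracle reaction energy", {
  gen <- small_synthetic()
  prov <- oracle_qm_provider(gen$truth)
  e_water <- attr(prov, "energy_fun")("O")
  de <- vapply(gen$dataset$records, function(r) {
    delta_e_rxn(attr(prov, "energy_fun")(r$product$smiles), e_water,
                attr(prov, "energy_fun")(r$acid$smiles),
                attr(prov, "energy_fun")(r$amine$smiles))
  }, numeric(1))
  expect_lt(cor(yields(gen$dataset), de), 0)
})
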