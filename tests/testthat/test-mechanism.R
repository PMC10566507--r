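test_that("amine classification matches the three-class definition", {
  expect_identical(classify_amine("CN"), "primary_aliphatic")
  expect_identical(classify_amine("Nc1ccccc1"), "primary_aromatic")
  expect_identical(classify_amine("CNC"), "secondary")
  expect_identical(classify_amine("NCc1ccccc1"), "primary_aliphatic") # benzylic
  expect_identical(classify_amine("C1CCNCC1"), "secondary")           # piperidine
  expect_error(classify_amine("CCO"), "no reactive amine")
  expect_error(classify_amine("CN(C)C"), "amine")
})

test_that("condensation is structurally forced and closed under validation", {
  expect_identical(condense_product("CC(=O)O", "CN")$smiles,
                   canonicalize("CNC(C)=O"))
  expect_identical(condense_product("OC=O", "N")$smiles, canonicalize("NC=O"))
  expect_error(condense_product("OC(=O)CC(=O)O", "CN"), "multiple carboxylic")
  expect_error(condense_product("CCO", "CN"), "no carboxylic")
  expect_error(condense_product("CC(=O)O", "CCO"), "no reactive amine")
})

test_that("O-acylisourea construction conserves mass and fixes the tautomer", {
  expect_identical(make_o_acylisourea("CC(=O)O", "DIC")$smiles,
                   canonicalize("CC(=O)OC(=NC(C)C)NC(C)C"))
  expect_identical(make_o_acylisourea("OC=O", "DCC")$smiles,
                   canonicalize("O=COC(=NC1CCCCC1)NC1CCCCC1"))
  # EDC: proton goes to the ethyl-side nitrogen (smaller substituent)
  edc <- make_o_acylisourea("CC(=O)O", "EDC")
  expect_identical(edc$smiles, canonicalize("CCNC(=NCCCN(C)C)OC(=O)C"))
  for (agent in c("EDC", "DCC", "DIC")) {
    inter <- make_o_acylisourea("OC(=O)CCc1ccccc1", agent)
    expected <- formula_add(mol_formula("OC(=O)CCc1ccccc1"),
                            mol_formula(amideml:::CARBODIIMIDES[[agent]]))
    expect_true(formula_equal(mol_formula(inter$smiles), expected))
  }
})

test_that("reaction centers are exactly the connectivity-changed atoms", {
  ctr <- annotate_reaction_centers("CC(=O)O", "CN", condense_product("CC(=O)O", "CN"))
  ga <- amideml:::parse_smiles(canonicalize("CC(=O)O"))
  expect_setequal(ga$elem[ctr$acid_atoms], c("C", "O"))
  gm <- amideml:::parse_smiles(canonicalize("CN"))
  expect_identical(gm$elem[ctr$amine_atoms], "N")
  gp <- amideml:::parse_smiles(condense_product("CC(=O)O", "CN")$smiles)
  expect_setequal(gp$elem[ctr$product_atoms], c("C", "N"))
  # atoms far from the amide bond never enter the center set
  big <- annotate_reaction_centers("OC(=O)CCc1ccccc1", "NCCc1ccccc1",
                                   condense_product("OC(=O)CCc1ccccc1",
                                                    "NCCc1ccccc1"))
  expect_length(big$acid_atoms, 2)
  expect_length(big$amine_atoms, 1)
  expect_length(big$product_atoms, 2)
})

test_that("center annotation is invariant to input atom renumbering", {
  # equivalent SMILES spellings renumber the atoms; annotation must agree
  spellings <- list(
    acid = c("OC(=O)CCc1ccccc1", "c1ccccc1CCC(O)=O"),
    amine = c("NCC", "CCN"))
  ref <- NULL
  for (a in spellings$acid) {
    for (m in spellings$amine) {
      ctr <- annotate_reaction_centers(a, m, condense_product(a, m))
      if (is.null(ref)) ref <- ctr
      expect_identical(ctr, ref)
    }
  }
})

test_that("a symmetric diamine reacting once is annotated consistently", {
  prod <- condense_product("CC(=O)O", "NCCCCN")
  ctr <- annotate_reaction_centers("CC(=O)O", "NCCCCN", prod)
  gm <- amideml:::parse_smiles(canonicalize("NCCCCN"))
  expect_identical(gm$elem[ctr$amine_atoms], "N")
})

test_that("augment_dataset fills intermediates that conserve mass", {
  ds <- subset_dataset(small_synthetic()$dataset, 1:10)
  aug <- augment_dataset(ds, centers = FALSE)
  for (r in aug$records) {
    expect_false(is.null(r$intermediate))
    expected <- formula_add(
      mol_formula(r$acid$smiles),
      mol_formula(amideml:::CARBODIIMIDES[[r$coupling_agent]]))
    expect_true(formula_equal(mol_formula(r$intermediate$smiles), expected))
  }
})
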