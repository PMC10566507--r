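test_that("canonicalization is idempotent and order-insensitive", {
  expect_identical(canonicalize("OC(=O)C"), canonicalize("CC(O)=O"))
  for (s in random_fragment_smiles(50, seed = 7)) {
    can <- canonicalize(s)
    expect_identical(canonicalize(can), can)
  }
})

test_that("malformed SMILES raise a parse error naming the input", {
  expect_error(canonicalize("C((("), "C\\(\\(\\(")
  expect_error(canonicalize("C1CC"), "unparseable")
  expect_error(canonicalize(""), "unparseable")
})

test_that("validate_record enforces the A + B = C + H2O pattern", {
  expect_length(validate_record(acetamide_record()), 0)

  ester <- acetamide_record()
  ester$product <- molecule("COC(C)=O", "product")
  expect_match(validate_record(ester), "formula mismatch", all = FALSE)

  bad_yield <- acetamide_record(yield = 120)
  expect_match(validate_record(bad_yield), "yield out of range", all = FALSE)

  bad_agent <- acetamide_record()
  bad_agent$coupling_agent <- "HATU"
  expect_match(validate_record(bad_agent), "coupling agent", all = FALSE)
})

test_that("reaction tables round-trip exactly through CSV", {
  gen <- small_synthetic()
  ds <- subset_dataset(gen$dataset, 1:25)
  # exercise the missing-value path too
  ds$records[[3]]$context$temperature <- NA_real_
  ds$records[[5]]$context$time <- NA_real_
  path <- withr::local_tempfile(fileext = ".csv")
  write_reaction_table(ds, path)
  back <- read_reaction_table(path)
  expect_identical(dataset_to_frame(back), dataset_to_frame(ds))
  expect_true(is.na(back$records[[3]]$context$temperature))
})

test_that("reading enforces schema and reports bad rows", {
  path <- withr::local_tempfile(fileext = ".csv")
  df <- dataset_to_frame(subset_dataset(small_synthetic()$dataset, 1:3))
  write.csv(df[, setdiff(names(df), "yield")], path, row.names = FALSE)
  expect_error(read_reaction_table(path), "yield")

  df2 <- df
  df2$acid_smiles[2] <- "C((("
  write.csv(df2, path, row.names = FALSE)
  expect_error(read_reaction_table(path), "row 2")

  # empty table with header -> empty dataset
  write.csv(df[0, ], path, row.names = FALSE)
  empty <- read_reaction_table(path)
  expect_length(empty$records, 0)
  expect_equal(empty$context_vocab$dimension, 0)
})

test_that("conformer I/O handles XYZ and atom-count mismatches", {
  path <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("3", "water energy=-76.4",
               "O 0.0 0.0 0.0", "H 0.96 0.0 0.0", "H -0.24 0.93 0.0"), path)
  conf <- read_conformer(path)
  expect_identical(conf$species, c("O", "H", "H"))
  expect_equal(nrow(conf$coords), 3)
  expect_equal(conf$energy, -76.4)

  writeLines(c("5", "broken", "O 0 0 0", "H 1 0 0", "H 0 1 0", "H 1 1 0"),
             path)
  expect_error(read_conformer(path), "declared 5")

  # round trip through the writer
  out <- withr::local_tempfile(fileext = ".xyz")
  write_conformer_xyz(conf, out)
  back <- read_conformer(out)
  expect_equal(back$coords, conf$coords, tolerance = 1e-7, ignore_attr = TRUE)
  expect_equal(back$energy, conf$energy)
})

test_that("context labels are normalized and vocabulary stays consistent", {
  ctx <- reaction_context(reagents = c("  DIPEA ", "hobt"), solvents = "DMF")
  expect_identical(ctx$reagents, c("dipea", "hobt"))
  vocab <- context_vocabulary(c("reagent:dipea", "reagent:hobt", "solvent:dmf"))
  v <- encode_context(ctx, vocab)
  expect_identical(v, c(1L, 1L, 1L))
  expect_identical(encode_context(reaction_context(), vocab), c(0L, 0L, 0L))
  # unknown labels contribute nothing
  v2 <- encode_context(reaction_context(solvents = "thf"), vocab)
  expect_identical(sum(v2), 0L)
})
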