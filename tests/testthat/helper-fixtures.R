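# Shared fixtures, memoised per test run. All molecular data is generated in
# code; nothing is read from disk.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) assign(name, build(), envir = .fixtures)
  .fixtures[[name]]
}

# a small synthetic dataset with planted structure, shared across files
small_synthetic <- function() {
  fixture("small_synthetic", function() {
    generate_dataset(generator_config(
      n_reactions = 200L, n_planted_cliffs = 10L, n_planted_uncertain = 5L,
      uncertain_group_size = 3L, seed = 42L))
  })
}

# one well-formed record: acetic acid + methylamine -> N-methylacetamide
acetamide_record <- function(yield = 80) {
  reaction_record(
    reaction_id = "r1",
    acid = molecule("CC(=O)O", "acid"),
    amine = molecule("CN", "amine"),
    product = molecule("CNC(C)=O", "product"),
    coupling_agent = "EDC",
    yield_percent = yield,
    context = reaction_context(reagents = "dipea", solvents = "dmf",
                               temperature = 25, time = 12))
}

# deterministic pseudo-random SMILES built from simple valid fragments
random_fragment_smiles <- function(n, seed = 1) {
  frags <- c("C", "CC", "CCC", "CCO", "CCN", "c1ccccc1", "C1CCCCC1",
             "CC(C)C", "COC", "CCS", "CC(=O)O", "CCCl", "CC(N)C",
             "Cc1ccccc1", "OCC", "NCC", "CNC", "CC=C", "C#N", "CC#N")
  set.seed(seed)
  sample(frags, n, replace = TRUE)
}
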