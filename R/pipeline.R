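# End-to-end orchestration: the default feature roster for stacking, the
# demo pipeline, and a manifest for reproducibility.

#' Build the four stacking descriptor blocks
#'
#' The default multimodal roster: Morgan fingerprints, the 2D battery, and
#' sum-pooled AEVs on embedded conformers, all over the acid and amine
#' roles, plus surrogate QM reaction features. Each block optionally carries
#' the context multi-hot slice so that every base model sees the reaction
#' conditions. The product role can be added but is redundant for
#' condensations (the product is determined by the reactant pair) and
#' multiplies featurization cost by the number of unique products.
#'
#' @param dataset A [reaction_dataset].
#' @param options A [featurize_options].
#' @param include_context Append the context slice to every block.
#' @param roles Molecule roles for the per-molecule blocks.
#' @param vocab Context vocabulary used for the slice.
#' @return Named list of [feature_block]s: `fingerprint`, `battery2d`,
#'   `aev`, `qm`.
#' @export
stack_feature_blocks <- function(dataset, options = featurize_options(),
                                 include_context = TRUE,
                                 roles = c("acid", "amine"),
                                 vocab = dataset$context_vocab) {
  ctx <- if (include_context) "context" else NULL
  list(
    fingerprint = assemble_reaction_features(
      dataset, c("fingerprint", ctx), roles, vocab = vocab, options = options),
    battery2d = assemble_reaction_features(
      dataset, c("battery2d", ctx), roles, vocab = vocab, options = options),
    aev = assemble_reaction_features(
      dataset, c("aev", ctx), intersect(roles, c("acid", "amine")),
      vocab = vocab, options = options),
    qm = assemble_reaction_features(
      dataset, c("qm", ctx), vocab = vocab, options = options))
}

#' Run the demo pipeline end to end
#'
#' generate -> augment (intermediates) -> featurize -> benchmark -> stack ->
#' cliff/uncertainty audit -> filtered re-evaluation. Artifacts (reaction
#' CSV, ground truth JSON, metric tables, cliff report, manifest) are
#' written under `out_dir`.
#'
#' @param config A [generator_config].
#' @param out_dir Output directory (created if missing).
#' @param specs Named list of [model_spec]s for the single-block benchmark
#'   grid (default: mean baseline and a random forest on fingerprints).
#' @param stack A [stack_spec].
#' @param plan A [split_plan].
#' @param options A [featurize_options] (pass an oracle-backed provider to
#'   use the generator's latent energies).
#' @param augment_intermediates Fill O-acylisourea intermediates first.
#' @return Invisibly, a list with the run artifacts.
#' @export
run_pipeline <- function(config = generator_config(n_reactions = 2000L),
                         out_dir = tempfile("amideml_run_"),
                         specs = list(baseline = model_spec("mean_baseline"),
                                      random_forest = model_spec("random_forest")),
                         stack = stack_spec(),
                         plan = split_plan(seed = config$seed),
                         options = NULL,
                         augment_intermediates = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  gen <- generate_dataset(config)
  dataset <- gen$dataset
  if (augment_intermediates) dataset <- augment_dataset(dataset, centers = FALSE)
  if (is.null(options)) {
    options <- featurize_options(qm_provider = oracle_qm_provider(gen$truth))
  }
  write_reaction_table(dataset, file.path(out_dir, "reactions.csv"))
  jsonlite::write_json(
    list(cliff_pairs = gen$truth$cliff_pairs,
         uncertain_groups = gen$truth$uncertain_groups,
         latent_yield = as.list(gen$truth$latent_yield)),
    file.path(out_dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)

  blocks <- stack_feature_blocks(dataset, options)
  y <- yields(dataset)
  grid <- run_benchmark(blocks["fingerprint"], y, specs, plan)
  utils::write.csv(grid, file.path(out_dir, "benchmark_grid.csv"),
                   row.names = FALSE)
  stack_res <- run_stack_benchmark(stack, blocks, y, plan)
  utils::write.csv(stack_res, file.path(out_dir, "stack_benchmark.csv"),
                   row.names = FALSE)
  report <- remove_and_reevaluate(
    dataset, function(d) stack_feature_blocks(d, options), stack, plan)
  utils::write.csv(report$cliff_pairs, file.path(out_dir, "cliff_pairs.csv"),
                   row.names = FALSE)
  utils::write.csv(
    data.frame(phase = c("before", "after"),
               n = c(report$n_before, report$n_after),
               r2_mean = c(mean(report$before$r2), mean(report$after$r2)),
               mae_mean = c(mean(report$before$mae), mean(report$after$mae))),
    file.path(out_dir, "removal_effect.csv"), row.names = FALSE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("amideml")),
    config = unclass(config),
    stages = c("generate", "augment", "featurize", "benchmark", "stack",
               "cliff_audit"),
    n_records = length(dataset$records))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(out_dir = out_dir, dataset = dataset, truth = gen$truth,
                 grid = grid, stack = stack_res, report = report))
}
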