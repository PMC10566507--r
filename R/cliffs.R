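# Reactivity-cliff and uncertain-record auditing: signature grouping,
# exact pairwise cosine scans, and filtered re-evaluation.

#' Canonical signature of a reaction
#'
#' Two records share a signature iff they are "the same reaction" in the
#' uncertainty sense: identical canonical acid/amine/product SMILES, coupling
#' agent, and normalized context (label lists order-insensitive, numeric
#' fields compared as values).
#'
#' @param record A [reaction_record].
#' @return A single character key.
#' @export
reaction_signature <- function(record) {
  ctx <- record$context
  paste(record$acid$smiles, record$amine$smiles, record$product$smiles,
        record$coupling_agent,
        paste(sort(ctx$reagents), collapse = ","),
        paste(sort(ctx$solvents), collapse = ","),
        paste(sort(ctx$conditions), collapse = ","),
        ifelse(is.na(ctx$temperature), "", format(ctx$temperature)),
        ifelse(is.na(ctx$time), "", format(ctx$time)),
        sep = "|")
}

#' Find uncertain (multiply-reported) reactions
#'
#' Groups records by [reaction_signature()] and reports groups of two or
#' more whose yields differ by more than `tolerance` (default 0: any
#' difference counts).
#'
#' @param dataset A [reaction_dataset].
#' @param tolerance Yield spread (max - min) that still counts as "the same
#'   yield", in points.
#' @return List of `uncertain_group` lists with fields `signature`,
#'   `reaction_ids`, `yields`, `spread`.
#' @export
find_uncertain <- function(dataset, tolerance = 0) {
  sigs <- vapply(dataset$records, reaction_signature, character(1))
  ids <- vapply(dataset$records, function(r) r$reaction_id, character(1))
  ys <- yields(dataset)
  out <- list()
  for (s in unique(sigs[duplicated(sigs)])) {
    ix <- which(sigs == s)
    spread <- max(ys[ix]) - min(ys[ix])
    if (length(ix) >= 2 && spread > tolerance) {
      grp <- list(signature = s, reaction_ids = ids[ix], yields = ys[ix],
                  spread = spread)
      class(grp) <- "uncertain_group"
      out[[length(out) + 1]] <- grp
    }
  }
  out
}

#' Cosine similarity between two feature rows
#'
#' @param features A [feature_block].
#' @param i,j Row indices.
#' @return Cosine similarity in `[-1, 1]`.
#' @export
pairwise_similarity <- function(features, i, j) {
  a <- features$matrix[i, ]; b <- features$matrix[j, ]
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("cosine similarity undefined for a zero vector")
  sum(a * b) / (na * nb)
}

#' Reaction-similarity feature space for cliff detection
#'
#' Concatenated acid + amine Morgan fingerprints plus the context multi-hot
#' slice — a reproducible vectorization of "similar reactants and context".
#'
#' @param dataset A [reaction_dataset].
#' @param options A [featurize_options].
#' @return A [feature_block].
#' @export
cliff_features <- function(dataset, options = featurize_options()) {
  assemble_reaction_features(dataset, blocks = c("fingerprint", "context"),
                             roles = c("acid", "amine"), options = options)
}

#' Detect reactivity cliffs
#'
#' Exact scan over all unordered record pairs: a pair is a cliff iff its
#' feature cosine similarity exceeds `sim_threshold`, its absolute yield
#' difference is at least `yield_gap` points, and the two records do not
#' share a signature (signature-identical duplicates are routed to
#' [find_uncertain()] instead). Equivalent to the brute-force O(n^2) scan;
#' implemented as a blocked normalized cross-product.
#'
#' @param dataset A [reaction_dataset].
#' @param features A row-aligned [feature_block] (see [cliff_features()]).
#' @param sim_threshold Cosine threshold (default 0.9, exclusive).
#' @param yield_gap Minimum yield difference in points (default 30,
#'   inclusive).
#' @return Data.frame of cliff pairs: `id_a`, `id_b`, `similarity`,
#'   `yield_gap`.
#' @export
find_cliffs <- function(dataset, features, sim_threshold = 0.9,
                        yield_gap = 30) {
  n <- length(dataset$records)
  if (nrow(features$matrix) != n) {
    stop("feature block is not row-aligned with the dataset")
  }
  ys <- yields(dataset)
  ids <- vapply(dataset$records, function(r) r$reaction_id, character(1))
  sigs <- vapply(dataset$records, reaction_signature, character(1))
  norms <- sqrt(rowSums(features$matrix^2))
  if (any(norms == 0)) stop("zero feature vector for record(s): ",
                            paste(ids[norms == 0], collapse = ", "))
  Xn <- features$matrix / norms
  out <- list()
  block <- 1024L
  for (start in seq(1, n, by = block)) {
    rows <- start:min(start + block - 1L, n)
    sims <- Xn[rows, , drop = FALSE] %*% t(Xn)
    for (ri in seq_along(rows)) {
      i <- rows[ri]
      if (i >= n) next
      js <- (i + 1):n
      hit <- js[sims[ri, js] > sim_threshold &
                  abs(ys[i] - ys[js]) >= yield_gap & sigs[js] != sigs[i]]
      if (length(hit) > 0) {
        out[[length(out) + 1]] <- data.frame(
          id_a = ids[i], id_b = ids[hit],
          similarity = sims[ri, hit], yield_gap = abs(ys[i] - ys[hit]),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(id_a = character(0), id_b = character(0),
                      similarity = numeric(0), yield_gap = numeric(0)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Remove flagged records and re-run the benchmark
#'
#' Detects cliffs and uncertain groups, removes every involved record, and
#' re-runs the identical stacking benchmark (same split plan seeds) on the
#' reduced dataset, reporting before/after metrics side by side.
#'
#' @param dataset A [reaction_dataset].
#' @param feature_fun Function `dataset -> named list of feature_blocks` used
#'   for the benchmark (re-applied to the reduced dataset).
#' @param stack A [stack_spec].
#' @param plan A [split_plan].
#' @param similarity_features Optional [feature_block] for the cliff scan
#'   (default: [cliff_features()] on the dataset).
#' @param sim_threshold,yield_gap,tolerance Detection thresholds.
#' @return A `cliff_report` list: `cliff_pairs`, `uncertain_groups`,
#'   `removal_ids`, `before`, `after` (per-split benchmark tables),
#'   `n_before`, `n_after`.
#' @export
remove_and_reevaluate <- function(dataset, feature_fun, stack = stack_spec(),
                                  plan = split_plan(),
                                  similarity_features = NULL,
                                  sim_threshold = 0.9, yield_gap = 30,
                                  tolerance = 0) {
  if (is.null(similarity_features)) similarity_features <- cliff_features(dataset)
  pairs <- find_cliffs(dataset, similarity_features, sim_threshold, yield_gap)
  groups <- find_uncertain(dataset, tolerance)
  removal <- union(unique(c(pairs$id_a, pairs$id_b)),
                   unique(unlist(lapply(groups, `[[`, "reaction_ids"))))
  ids <- vapply(dataset$records, function(r) r$reaction_id, character(1))
  keep <- which(!ids %in% removal)
  reduced <- subset_dataset(dataset, keep)
  if (length(reduced$records) < 20) {
    stop("removal leaves too few records (", length(reduced$records), ")")
  }
  before <- run_stack_benchmark(stack, feature_fun(dataset), yields(dataset),
                                plan)
  after <- run_stack_benchmark(stack, feature_fun(reduced), yields(reduced),
                               plan)
  out <- list(cliff_pairs = pairs, uncertain_groups = groups,
              removal_ids = removal, before = before, after = after,
              n_before = length(dataset$records),
              n_after = length(reduced$records))
  class(out) <- "cliff_report"
  out
}

#' @export
print.cliff_report <- function(x, ...) {
  cat("<cliff_report>\n",
      "  cliff pairs: ", nrow(x$cliff_pairs), "\n",
      "  uncertain groups: ", length(x$uncertain_groups),
      " (", sum(vapply(x$uncertain_groups, function(g) length(g$reaction_ids),
                       numeric(1))), " records)\n",
      "  removed: ", length(x$removal_ids), " of ", x$n_before, "\n",
      "  mean test R2 before: ", round(mean(x$before$r2), 3),
      "  after: ", round(mean(x$after$r2), 3), "\n", sep = "")
  invisible(x)
}
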