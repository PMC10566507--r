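# Connectivity-derived descriptors: 2D physicochemical battery, context
# encoding, feature-matrix assembly and selection.

ATOMIC_MASS <- c(H = 1.008, B = 10.811, C = 12.011, N = 14.007, O = 15.999,
                 F = 18.998, Si = 28.086, P = 30.974, S = 32.06, Cl = 35.453,
                 Br = 79.904, I = 126.904)
PAULING_EN <- c(H = 2.20, B = 2.04, C = 2.55, N = 3.04, O = 3.44, F = 3.98,
                Si = 1.90, P = 2.19, S = 2.58, Cl = 3.16, Br = 2.96, I = 2.66)
COVALENT_RADIUS <- c(H = 0.31, B = 0.84, C = 0.76, N = 0.71, O = 0.66,
                     F = 0.57, Si = 1.11, P = 1.07, S = 1.05, Cl = 1.02,
                     Br = 1.20, I = 1.39)

#' A named feature matrix for one descriptor family
#'
#' @param name Block name, e.g. `"fingerprint"`, `"battery2d"`, `"aev"`,
#'   `"qm"`, `"context"`, `"steric"` or a merge of them.
#' @param matrix Numeric matrix, rows = reactions (in dataset record order),
#'   columns = features.
#' @param feature_names Optional column labels (default: matrix colnames).
#' @return An object of class `feature_block`.
#' @export
feature_block <- function(name, matrix, feature_names = colnames(matrix)) {
  matrix <- as.matrix(matrix)
  if (is.null(feature_names)) {
    feature_names <- paste0(name, "_", seq_len(ncol(matrix)))
  }
  if (anyDuplicated(feature_names)) stop("feature names must be unique")
  if (length(feature_names) != ncol(matrix)) {
    stop("feature_names length does not match column count")
  }
  colnames(matrix) <- feature_names
  obj <- list(name = name, matrix = matrix, feature_names = feature_names)
  class(obj) <- "feature_block"
  obj
}

#' @export
print.feature_block <- function(x, ...) {
  cat("<feature_block:", x$name, "> ", nrow(x$matrix), " x ", ncol(x$matrix), "\n",
      sep = "")
  invisible(x)
}

# --- 2D descriptor battery ---------------------------------------------------

AUTOCORR_PROPS <- c("mass", "en", "crad", "hcount", "degree", "hetero")
AUTOCORR_LAGS <- 1:8

battery_2d_names <- function() {
  base <- c("n_atoms", "n_heavy", "n_H", "mol_weight", "mean_atomic_mass",
            paste0("count_", c("C", "N", "O", "F", "Si", "P", "S", "Cl", "Br", "I")),
            "n_bonds_heavy", "n_single", "n_double", "n_triple", "n_pi_electrons",
            "n_rings", "n_ring_atoms", "n_aromatic_C", "n_rotatable",
            "n_HBD", "n_HBA", "n_halogen", "n_heteroatoms",
            "frac_sp3_C", "n_sp2_C", "sum_abs_charge",
            paste0("deg_count_", 1:4),
            "wiener_index", "zagreb_m1", "zagreb_m2", "randic_chi1",
            "chi0", "chi2", "balaban_j", "topo_diameter", "topo_radius",
            "mean_eccentricity", "kappa1", "kappa2",
            "estate_sum", "estate_mean", "estate_max", "estate_min",
            paste0("fg_", c("carboxyl", "amine_site", "amide", "hydroxyl",
                            "ether", "nitrile", "aryl_halide", "methyl", "methoxy")))
  auto <- as.vector(outer(AUTOCORR_LAGS, AUTOCORR_PROPS, function(l, p) {
    paste0("ats_", p, "_", l)
  }))
  moran <- sub("^ats", "moran", auto)
  geary <- sub("^ats", "geary", auto)
  c(base, auto, moran, geary)
}

#' 2D physicochemical and topological descriptor battery
#'
#' A fixed battery of >200 named connectivity-derived descriptors spanning
#' constitutional counts, ring/rotor/H-bond counts, topological indices
#' (Wiener, Zagreb, Randic/chi, Balaban J, kappa shape), Kier-Hall
#' electrotopological-state summaries, functional-group counts, and
#' Moreau-Broto / Moran / Geary autocorrelations (lags 1-8) over atomic mass,
#' electronegativity, covalent radius, hydrogen count, degree and
#' heteroatom indicator. Descriptors undefined for a molecule (e.g. spatial
#' autocorrelation of a constant property) are `NaN` and are expected to be
#' removed by [variance_filter()].
#'
#' @param mol A [molecule] or SMILES string.
#' @return Named numeric vector, identical length and ordering for every
#'   molecule.
#' @export
battery_2d <- function(mol) {
  smiles <- if (inherits(mol, "molecule")) mol$smiles else canonicalize(mol)
  cache_fetch(paste0("b2d::", smiles), function() battery_2d_impl(smiles))
}

battery_2d_impl <- function(smiles) {
  g <- parse_smiles(smiles)
  h <- heavy_view(g)
  out <- stats::setNames(numeric(length(battery_2d_names())), battery_2d_names())
  deg <- vapply(h$adj, function(m) length(g_rows(m)), numeric(1))
  borders <- if (h$n > 1) unlist(lapply(seq_len(h$n), function(i) {
    nb <- h$adj[[i]]; if (is.null(nb)) numeric(0) else nb[nb[, 1] > i, 2]
  })) else numeric(0)

  out["n_atoms"] <- g$n
  out["n_heavy"] <- h$n
  out["n_H"] <- g$n - h$n
  out["mol_weight"] <- sum(ATOMIC_MASS[g$elem])
  out["mean_atomic_mass"] <- out["mol_weight"] / g$n
  for (e in c("C", "N", "O", "F", "Si", "P", "S", "Cl", "Br", "I")) {
    out[paste0("count_", e)] <- sum(g$elem == e)
  }
  out["n_bonds_heavy"] <- length(borders)
  out["n_single"] <- sum(borders == 1)
  out["n_double"] <- sum(borders == 2)
  out["n_triple"] <- sum(borders == 3)
  out["n_pi_electrons"] <- 2 * sum(borders == 2) + 4 * sum(borders == 3)
  out["n_rings"] <- length(borders) - h$n + n_components(h)
  out["n_ring_atoms"] <- sum(h$ring)
  out["n_aromatic_C"] <- sum(vapply(g$heavy, function(i) is_aromatic_carbon(g, i),
                                    logical(1)))
  out["n_rotatable"] <- n_rotatable(h, deg)
  out["n_HBD"] <- sum(h$elem %in% c("N", "O") & h$hcount > 0)
  out["n_HBA"] <- sum(h$elem %in% c("N", "O"))
  out["n_halogen"] <- sum(h$elem %in% c("F", "Cl", "Br", "I"))
  out["n_heteroatoms"] <- sum(!h$elem %in% c("C", "H"))
  is_sp3C <- h$elem == "C" &
    vapply(h$adj, function(m) is.null(m) || all(m[, 2] == 1), logical(1))
  out["frac_sp3_C"] <- if (sum(h$elem == "C") > 0) {
    sum(is_sp3C) / sum(h$elem == "C")
  } else NaN
  out["n_sp2_C"] <- sum(h$elem == "C" &
    vapply(h$adj, function(m) !is.null(m) && sum(m[, 2] == 2) == 1, logical(1)))
  out["sum_abs_charge"] <- sum(abs(h$charge))
  for (d in 1:4) out[paste0("deg_count_", d)] <- sum(deg == d)

  # topological indices on the heavy-atom graph
  if (h$n >= 2) {
    D <- heavy_distance_matrix(h)
    finite <- is.finite(D)
    out["wiener_index"] <- sum(D[upper.tri(D)][is.finite(D[upper.tri(D)])])
    out["zagreb_m1"] <- sum(deg^2)
    out["zagreb_m2"] <- sum_over_bonds(h, function(i, j, o) deg[i] * deg[j])
    out["randic_chi1"] <- sum_over_bonds(h, function(i, j, o) 1 / sqrt(deg[i] * deg[j]))
    out["chi0"] <- sum(1 / sqrt(deg[deg > 0]))
    out["chi2"] <- chi2_index(h, deg)
    out["balaban_j"] <- balaban_j(h, D, deg)
    ecc <- apply(D, 1, function(r) max(r[is.finite(r)]))
    out["topo_diameter"] <- max(ecc)
    out["topo_radius"] <- min(ecc)
    out["mean_eccentricity"] <- mean(ecc)
    p1 <- length(borders)
    p2 <- sum(choose(deg, 2))
    out["kappa1"] <- if (p1 > 0) h$n * (h$n - 1)^2 / p1^2 else NaN
    out["kappa2"] <- if (p2 > 0) (h$n - 1) * (h$n - 2)^2 / p2^2 else NaN
  } else {
    out[c("wiener_index", "zagreb_m1", "zagreb_m2", "randic_chi1", "chi0",
          "chi2", "balaban_j", "topo_diameter", "topo_radius",
          "mean_eccentricity", "kappa1", "kappa2")] <- NaN
  }

  es <- estate_intrinsic(h, deg)
  out["estate_sum"] <- sum(es)
  out["estate_mean"] <- mean(es)
  out["estate_max"] <- max(es)
  out["estate_min"] <- min(es)

  out["fg_carboxyl"] <- length(find_carboxyl_groups(g))
  out["fg_amine_site"] <- length(find_amine_sites(g))
  out["fg_amide"] <- count_amides(h)
  out["fg_hydroxyl"] <- sum(h$elem == "O" & h$hcount == 1 & deg == 1)
  out["fg_ether"] <- sum(h$elem == "O" & h$hcount == 0 & deg == 2 &
    vapply(h$adj, function(m) !is.null(m) && all(m[, 2] == 1), logical(1)))
  out["fg_nitrile"] <- sum(h$elem == "N" &
    vapply(h$adj, function(m) !is.null(m) && any(m[, 2] == 3), logical(1)))
  out["fg_aryl_halide"] <- sum(vapply(which(h$elem %in% c("F", "Cl", "Br", "I")),
    function(i) {
      nb <- h$adj[[i]]
      !is.null(nb) && any(vapply(nb[, 1], function(j) {
        is_aromatic_carbon(g, g$heavy[j])
      }, logical(1)))
    }, logical(1)))
  out["fg_methyl"] <- sum(h$elem == "C" & h$hcount == 3 & deg == 1)
  out["fg_methoxy"] <- sum(vapply(which(h$elem == "O" & deg == 2), function(i) {
    nb <- h$adj[[i]]
    any(h$elem[nb[, 1]] == "C" & h$hcount[nb[, 1]] == 3)
  }, logical(1)))

  # spatial autocorrelations over the topological distance matrix
  props <- list(mass = ATOMIC_MASS[h$elem], en = PAULING_EN[h$elem],
                crad = COVALENT_RADIUS[h$elem], hcount = h$hcount,
                degree = deg, hetero = as.numeric(!h$elem %in% c("C", "H")))
  if (h$n >= 2) {
    D <- heavy_distance_matrix(h)
    for (p in AUTOCORR_PROPS) {
      v <- unname(props[[p]])
      vc <- v - mean(v)
      varv <- sum(vc^2) / h$n
      for (l in AUTOCORR_LAGS) {
        pairs <- which(D == l, arr.ind = TRUE)
        pairs <- pairs[pairs[, 1] < pairs[, 2], , drop = FALSE]
        np <- nrow(pairs)
        out[paste0("ats_", p, "_", l)] <- if (np > 0) {
          sum(v[pairs[, 1]] * v[pairs[, 2]])
        } else 0
        out[paste0("moran_", p, "_", l)] <- if (np > 0 && varv > 0) {
          (sum(vc[pairs[, 1]] * vc[pairs[, 2]]) / np) / varv
        } else NaN
        out[paste0("geary_", p, "_", l)] <- if (np > 0 && varv > 0) {
          (sum((v[pairs[, 1]] - v[pairs[, 2]])^2) / (2 * np)) /
            (sum(vc^2) / (h$n - 1))
        } else NaN
      }
    }
  } else {
    out[grep("^(ats|moran|geary)_", names(out))] <- NaN
  }
  out
}

heavy_edgelist <- function(h) {
  do.call(rbind, lapply(seq_len(h$n), function(i) {
    nb <- h$adj[[i]]
    if (is.null(nb)) return(NULL)
    js <- nb[nb[, 1] > i, 1]
    if (length(js) == 0) return(NULL)
    cbind(rep(i, length(js)), js)
  }))
}

n_components <- function(h) {
  if (h$n == 0) return(0L)
  el <- heavy_edgelist(h)
  if (is.null(el) || nrow(el) == 0) return(h$n)
  ig <- igraph::graph_from_edgelist(el, directed = FALSE)
  if (igraph::vcount(ig) < h$n) ig <- igraph::add_vertices(ig, h$n - igraph::vcount(ig))
  igraph::components(ig)$no
}

heavy_distance_matrix <- function(h) {
  el <- heavy_edgelist(h)
  ig <- if (is.null(el) || nrow(el) == 0) {
    igraph::make_empty_graph(h$n, directed = FALSE)
  } else {
    g0 <- igraph::graph_from_edgelist(el, directed = FALSE)
    if (igraph::vcount(g0) < h$n) igraph::add_vertices(g0, h$n - igraph::vcount(g0)) else g0
  }
  igraph::distances(ig)
}

sum_over_bonds <- function(h, f) {
  total <- 0
  for (i in seq_len(h$n)) {
    nb <- h$adj[[i]]
    if (is.null(nb)) next
    for (r in seq_len(nrow(nb))) {
      if (nb[r, 1] > i) total <- total + f(i, nb[r, 1], nb[r, 2])
    }
  }
  total
}

chi2_index <- function(h, deg) {
  total <- 0
  for (j in seq_len(h$n)) {
    nb <- h$adj[[j]]
    if (is.null(nb) || nrow(nb) < 2) next
    ns <- nb[, 1]
    for (a in seq_len(length(ns) - 1)) {
      for (b in (a + 1):length(ns)) {
        total <- total + 1 / sqrt(deg[ns[a]] * deg[j] * deg[ns[b]])
      }
    }
  }
  total
}

balaban_j <- function(h, D, deg) {
  m <- sum(deg) / 2
  mu <- m - h$n + n_components(h)
  if (m == 0) return(NaN)
  s <- rowSums(ifelse(is.finite(D), D, 0))
  acc <- sum_over_bonds(h, function(i, j, o) 1 / sqrt(s[i] * s[j]))
  m / (mu + 1) * acc
}

# Kier-Hall intrinsic state I = ((2/L)^2 * Zv + 1) / delta, L = principal
# quantum number, Zv = valence electrons, delta = heavy-atom degree.
estate_intrinsic <- function(h, deg) {
  ZV <- c(H = 1, B = 3, C = 4, N = 5, O = 6, F = 7, Si = 4, P = 5, S = 6,
          Cl = 7, Br = 7, I = 7)
  LQ <- c(H = 1, B = 2, C = 2, N = 2, O = 2, F = 2, Si = 3, P = 3, S = 3,
          Cl = 3, Br = 4, I = 5)
  d <- pmax(deg, 1)
  ((2 / LQ[h$elem])^2 * ZV[h$elem] + 1) / d
}

count_amides <- function(h) {
  total <- 0
  for (i in which(h$elem == "C")) {
    nb <- h$adj[[i]]
    if (is.null(nb)) next
    has_o <- any(nb[, 2] == 2 & h$elem[nb[, 1]] == "O")
    has_n <- any(nb[, 2] == 1 & h$elem[nb[, 1]] == "N")
    if (has_o && has_n) total <- total + 1
  }
  total
}

n_rotatable <- function(h, deg) {
  count <- 0
  for (i in seq_len(h$n)) {
    nb <- h$adj[[i]]
    if (is.null(nb)) next
    for (r in seq_len(nrow(nb))) {
      j <- nb[r, 1]
      if (j <= i || nb[r, 2] != 1) next
      if (h$ring[i] && h$ring[j]) next
      if (deg[i] > 1 && deg[j] > 1) count <- count + 1
    }
  }
  count
}

# --- context encoding --------------------------------------------------------

#' Build a context vocabulary from a set of records
#'
#' @param records List of [reaction_record]s (typically the training fold).
#' @return A [context_vocabulary] over all labels observed, sorted.
#' @export
build_context_vocab <- function(records) {
  labs <- unique(unlist(lapply(records, function(r) context_labels(r$context))))
  context_vocabulary(sort(labs %||% character(0)))
}

#' Multi-hot encode a reaction context
#'
#' Position `i` is 1 iff vocabulary label `i` applies to the reaction, across
#' the reagent, solvent and condition fields. Labels absent from the
#' vocabulary (e.g. unseen at training time) contribute nothing.
#'
#' @param ctx A [reaction_context].
#' @param vocab A [context_vocabulary].
#' @return Integer 0/1 vector of length `vocab$dimension`.
#' @export
encode_context <- function(ctx, vocab) {
  v <- integer(vocab$dimension)
  v[match(context_labels(ctx), vocab$labels, nomatch = 0L)] <- 1L
  v
}

# --- assembly ----------------------------------------------------------------

#' Featurization options
#'
#' Bundles the tunables used when assembling reaction feature matrices.
#'
#' @param fp_radius,fp_bits Morgan fingerprint parameters.
#' @param aev_params An [aev_params] object.
#' @param steric_params A [steric_params] object.
#' @param qm_provider A QM provider function (see [heuristic_qm_provider()]).
#' @param embed_seed Base seed for conformer embedding.
#' @param embed_k Number of seeded embeddings to try per molecule.
#' @return A list of class `featurize_options`.
#' @export
featurize_options <- function(fp_radius = 2L, fp_bits = 2048L,
                              aev_params = aev_params_default(),
                              steric_params = steric_params_default(),
                              qm_provider = heuristic_qm_provider(),
                              embed_seed = 20260101L, embed_k = 4L) {
  obj <- list(fp_radius = fp_radius, fp_bits = fp_bits, aev_params = aev_params,
              steric_params = steric_params, qm_provider = qm_provider,
              embed_seed = embed_seed, embed_k = embed_k)
  class(obj) <- "featurize_options"
  obj
}

role_molecule <- function(record, role) {
  m <- record[[role]]
  if (is.null(m)) {
    stop("reaction ", record$reaction_id, " lacks a ", role, " molecule")
  }
  m
}

# descriptor matrix over unique SMILES, expanded to one row per record
per_molecule_matrix <- function(dataset, roles, fun, prefix) {
  if (length(roles) == 0) stop("role list must not be empty")
  cols <- lapply(roles, function(role) {
    smis <- vapply(dataset$records, function(r) role_molecule(r, role)$smiles,
                   character(1))
    uni <- unique(smis)
    desc <- lapply(uni, fun)
    width <- length(desc[[1]])
    m <- do.call(rbind, desc)[match(smis, uni), , drop = FALSE]
    nm <- names(desc[[1]]) %||% seq_len(width)
    colnames(m) <- paste0(role, "_", prefix, "_", nm)
    m
  })
  do.call(cbind, cols)
}

#' Assemble a reaction-level feature matrix
#'
#' Per reaction, concatenates per-molecule descriptors over the requested
#' roles, then per-reaction blocks, then (optionally) the context multi-hot
#' slice. Column provenance is recorded in the feature names
#' (`<role>_<block>_<feature>`).
#'
#' @param dataset A [reaction_dataset].
#' @param blocks Character vector from `"fingerprint"`, `"battery2d"`,
#'   `"aev"`, `"qm"`, `"steric"`, `"context"`.
#' @param roles Molecule roles for per-molecule blocks; default acid, amine,
#'   product.
#' @param vocab Context vocabulary for the `"context"` block (defaults to the
#'   dataset's; pass the training-fold vocabulary to avoid leakage).
#' @param options A [featurize_options] bundle.
#' @return A [feature_block] named by the joined block list.
#' @export
assemble_reaction_features <- function(dataset,
                                       blocks = "fingerprint",
                                       roles = c("acid", "amine", "product"),
                                       vocab = dataset$context_vocab,
                                       options = featurize_options()) {
  known <- c("fingerprint", "battery2d", "aev", "qm", "steric", "context")
  bad <- setdiff(blocks, known)
  if (length(bad) > 0) stop("unknown feature block(s): ", paste(bad, collapse = ", "))
  if (length(blocks) == 0) stop("block list must not be empty")
  parts <- lapply(blocks, function(b) {
    switch(b,
      fingerprint = per_molecule_matrix(dataset, roles, function(s) {
        stats::setNames(morgan_fingerprint(s, options$fp_radius, options$fp_bits),
                        paste0("bit", seq_len(options$fp_bits)))
      }, "fp"),
      battery2d = per_molecule_matrix(dataset, roles, battery_2d, "b2d"),
      aev = per_molecule_matrix(dataset, roles, function(s) {
        conf <- embed_conformer(s, seed = options$embed_seed, k = options$embed_k)
        pool_aev(compute_aev(conf, options$aev_params))
      }, "aev"),
      qm = qm_block_matrix(dataset, options),
      steric = steric_block_matrix(dataset, options),
      context = {
        m <- t(vapply(dataset$records,
                      function(r) encode_context(r$context, vocab),
                      integer(vocab$dimension)))
        if (vocab$dimension == 0) m <- matrix(0L, length(dataset$records), 0)
        colnames(m) <- if (vocab$dimension > 0) paste0("ctx_", vocab$labels)
        m
      })
  })
  m <- do.call(cbind, parts)
  rownames(m) <- vapply(dataset$records, function(r) r$reaction_id, character(1))
  feature_block(paste(blocks, collapse = "+"), m)
}

# --- filtering and selection -------------------------------------------------

#' Fit a variance filter on a feature matrix
#'
#' @param matrix Numeric matrix (training rows).
#' @param threshold Minimum variance to keep a column; columns containing
#'   missing values are always dropped.
#' @return Integer vector of retained column indices.
#' @export
fit_variance_filter <- function(matrix, threshold = 0) {
  if (threshold < 0) stop("variance threshold must be >= 0")
  ok_na <- colSums(!is.finite(matrix)) == 0
  v <- rep(NA_real_, ncol(matrix))
  v[ok_na] <- apply(matrix[, ok_na, drop = FALSE], 2, stats::var)
  keep <- which(ok_na & v >= threshold)
  if (length(keep) == 0) stop("variance filter removed every column")
  keep
}

#' Variance-filter a feature block
#'
#' Removes columns with variance below `threshold` and columns containing
#' missing values; retained column order is preserved. Idempotent.
#'
#' @param block A [feature_block].
#' @param threshold Minimum variance (default 0: drop only missing-value
#'   columns).
#' @return The filtered [feature_block].
#' @export
variance_filter <- function(block, threshold = 0) {
  keep <- fit_variance_filter(block$matrix, threshold)
  feature_block(block$name, block$matrix[, keep, drop = FALSE])
}

#' Recursive feature elimination plan
#'
#' @param targets Named integer vector: target feature count per block name.
#' @param step_frac Fraction of remaining columns dropped per round.
#' @param num_trees Trees in the ranking forest.
#' @param seed Seed for the ranking model.
#' @return An object of class `selection_plan`.
#' @export
selection_plan <- function(targets, step_frac = 0.1, num_trees = 100L,
                           seed = 1L) {
  stopifnot(all(targets >= 1))
  obj <- list(targets = targets, step_frac = step_frac,
              num_trees = as.integer(num_trees), seed = as.integer(seed))
  class(obj) <- "selection_plan"
  obj
}

rfe_one_block <- function(X, y, target, plan) {
  if (target > ncol(X)) stop("RFE target ", target, " exceeds block width ", ncol(X))
  keep <- seq_len(ncol(X))
  while (length(keep) > target) {
    df <- data.frame(X[, keep, drop = FALSE], y = y, check.names = FALSE)
    fit <- ranger::ranger(y ~ ., data = df, num.trees = plan$num_trees,
                          importance = "impurity", seed = plan$seed,
                          num.threads = 1)
    imp <- fit$variable.importance
    drop_n <- max(1L, min(length(keep) - target,
                          floor(plan$step_frac * length(keep))))
    drop_idx <- order(imp, decreasing = FALSE)[seq_len(drop_n)]
    keep <- keep[-drop_idx]
  }
  keep
}

#' Select features per block by recursive elimination and merge
#'
#' For each block, a seeded random-forest ranking model is refit each round
#' and the lowest-importance features (10% of the remainder by default) are
#' dropped until the block's target count remains; the surviving columns of
#' all blocks are then concatenated.
#'
#' @param blocks Named list of [feature_block]s (names matching
#'   `plan$targets`).
#' @param y Yield vector aligned with the blocks' rows.
#' @param plan A [selection_plan].
#' @return A merged [feature_block] named `"merged"`.
#' @export
rfe_select <- function(blocks, y, plan) {
  sel <- lapply(names(plan$targets), function(nm) {
    blk <- blocks[[nm]]
    if (is.null(blk)) stop("no feature block named ", nm)
    keep <- rfe_one_block(blk$matrix, y, plan$targets[[nm]], plan)
    blk$matrix[, keep, drop = FALSE]
  })
  feature_block("merged", do.call(cbind, sel))
}
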