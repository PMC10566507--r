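# Synthetic literature-like amide-coupling datasets with known ground truth:
# a latent structure-yield function over real (generated) molecules, planted
# reactivity cliffs, planted uncertain records, categorical context effects,
# and latent per-molecule electronic energies giving a weak negative
# yield-dE_rxn correlation.

#' Generator configuration
#'
#' Defaults emulate a literature amide-coupling dataset: a high-yield-skewed
#' distribution with mean 64.1%, three amine classes, a categorical context
#' vocabulary, planted reactivity cliffs (structurally near-identical pairs
#' with >= 30-point yield gaps), planted uncertain records (the same reaction
#' reported with several yields spanning roughly 30-90%), additive Gaussian
#' yield noise (s.d. 8 points, clipped to [0, 100]) and a target yield-dE_rxn
#' correlation of -0.12.
#'
#' @param n_reactions Total records emitted.
#' @param n_acids,n_amines_per_class Fragment library sizes.
#' @param mean_yield Target mean of the latent yields (%).
#' @param yield_noise_sd S.d. of the additive observation noise (%).
#' @param n_solvents,n_reagents,n_conditions Context vocabulary sizes.
#' @param n_planted_cliffs Number of planted cliff pairs (default 3% of
#'   `n_reactions`, i.e. 150 at the default size).
#' @param cliff_gap Minimum observed yield gap within a planted pair (%).
#' @param n_planted_uncertain Number of planted uncertain groups (default
#'   0.8% of `n_reactions`, i.e. 40 at the default size).
#' @param uncertain_group_size Records per uncertain group.
#' @param uncertain_span Yield range the uncertain records are drawn from.
#' @param target_de_corr Target Pearson correlation between yield and dE_rxn.
#' @param seed Integer seed; the whole dataset is a deterministic function of
#'   the configuration.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_reactions = 5000L, n_acids = 60L,
                             n_amines_per_class = 20L, mean_yield = 64.1,
                             yield_noise_sd = 8, n_solvents = 10L,
                             n_reagents = 8L, n_conditions = 5L,
                             n_planted_cliffs = round(0.03 * n_reactions),
                             cliff_gap = 30,
                             n_planted_uncertain = round(0.008 * n_reactions),
                             uncertain_group_size = 3L,
                             uncertain_span = c(30, 90),
                             target_de_corr = -0.12, seed = 0L) {
  if (cliff_gap <= 0 || cliff_gap > 100) stop("cliff_gap must be in (0, 100]")
  if (abs(target_de_corr) >= 1) stop("target correlation must be in (-1, 1)")
  if (2 * n_planted_cliffs + n_planted_uncertain * uncertain_group_size >
      n_reactions) {
    stop("planted structure exceeds n_reactions")
  }
  obj <- as.list(environment())
  class(obj) <- "generator_config"
  obj
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# --- fragment library --------------------------------------------------------

enumerate_acid_pool <- function() {
  out <- character(0)
  chain <- function(k) paste(rep("C", k), collapse = "")
  # linear and branched aliphatic acids
  for (k in 1:8) out <- c(out, paste0(chain(k), "C(=O)O"))
  for (k in 0:3) out <- c(out, paste0("CC(C)", chain(k), "C(=O)O"))
  for (k in 0:2) out <- c(out, paste0("C1CCCCC1", chain(k), "C(=O)O"))
  # para-substituted phenylalkanoic acids
  subst <- c(H = "", F = "F", Cl = "Cl", Me = "C", OMe = "OC", CN = "N#C")
  for (x in names(subst)) {
    for (k in 1:4) {
      ring <- if (x == "H") "c1ccccc1" else paste0("c1ccc(", subst[[x]], ")cc1")
      out <- c(out, paste0("OC(=O)", chain(k), ring))
    }
  }
  out <- c(out, names(cliff_editable_acids()))
  # ether / thioether acids
  for (k in 2:5) out <- c(out, paste0("CO", chain(k), "C(=O)O"))
  for (k in 2:4) out <- c(out, paste0("CS", chain(k), "C(=O)O"))
  # difunctional-substituent variants (extra halogens on the ring)
  for (k in 1:3) {
    out <- c(out, paste0("OC(=O)", chain(k), "c1ccc(F)c(F)c1"))
    out <- c(out, paste0("OC(=O)", chain(k), "c1ccc(Cl)c(Cl)c1"))
  }
  unique(canonicalize(out))
}

# Drug-like benzyl-ether acids with a distal para-H ring: a methyl edit
# there sits >= 4 bonds from the carboxyl carbon and perturbs only a small
# fraction of the fingerprint, so the edited pair stays cosine-similar.
cliff_editable_acids <- function() {
  chain <- function(k) paste(rep("C", k), collapse = "")
  base <- c(vapply(3:5, function(k) {
    paste0("OC(=O)", chain(k), "c1ccc(OCc2ccccc2)cc1")
  }, character(1)), "OC(=O)CCCc1cc(OC)ccc1OCc2ccccc2")
  edited <- sub("c2ccccc2", "c2ccc(C)cc2", base, fixed = TRUE)
  stats::setNames(canonicalize(edited), canonicalize(base))
}

enumerate_amine_pool <- function() {
  chain <- function(k) paste(rep("C", k), collapse = "")
  aliphatic <- character(0)
  for (k in 1:8) aliphatic <- c(aliphatic, paste0("N", chain(k)))
  for (k in 0:3) aliphatic <- c(aliphatic, paste0("NC", chain(k), "(C)C"))
  aliphatic <- c(aliphatic, "NCC1CCCCC1", "NC1CCCCC1", "NCCC1CCCCC1")
  subst <- c("", "F", "Cl", "C", "OC")
  for (x in subst) {
    ring <- if (x == "") "c1ccccc1" else paste0("c1ccc(", x, ")cc1")
    aliphatic <- c(aliphatic, paste0("NC", ring), paste0("NCC", ring))
  }
  aromatic <- character(0)
  for (x in c("", "F", "Cl", "C", "OC", "CC", "CCC")) {
    ring <- if (x == "") "Nc1ccccc1" else paste0("Nc1ccc(", x, ")cc1")
    aromatic <- c(aromatic, ring)
  }
  aromatic <- c(aromatic,
                "Nc1cccc(F)c1", "Nc1cccc(Cl)c1", "Nc1cccc(C)c1",
                "Nc1ccc2ccccc2c1", "Nc1ccc(OCC)cc1", "Nc1ccc(SC)cc1",
                "Nc1ccc(CC(C)C)cc1", "Nc1cccc(OC)c1", "Cc1ccc(N)cc1C",
                "Nc1ccc(F)c(C)c1", "Nc1ccc(Cl)c(C)c1", "Nc1ccc(C(C)C)cc1",
                "Nc1ccc(OC(C)C)cc1")
  secondary <- c("CNC", "CNCC", "CNCCC", "CCNCC", "CNCCCC", "CCNCCC",
                 "C1CCNCC1", "C1CCNC1", "O1CCNCC1", "CNC1CCCCC1",
                 "CNCc1ccccc1", "CCNCc1ccccc1", "CNCCc1ccccc1",
                 "C1CCCNCC1", "CC(C)NC", "CC(C)NCC", "CCC(C)NC",
                 "CNCCOC", "CNCCCOC", "C1CNCCC1C")
  list(primary_aliphatic = unique(canonicalize(aliphatic)),
       primary_aromatic = unique(canonicalize(aromatic)),
       secondary = unique(canonicalize(secondary)))
}

#' Build a seeded fragment library
#'
#' Samples the requested numbers of mono-carboxylic acids and amines (equal
#' counts of the three amine classes) from fixed, programmatically enumerated
#' pools. Every acid has exactly one carboxyl group; every amine classifies
#' into exactly one class.
#'
#' @param config A [generator_config].
#' @param seed Seed (defaults to the config's).
#' @return List with `acids`, `amines`, `amine_class` (aligned to `amines`),
#'   and `cliff_edit`, a named map from editable acid SMILES to its
#'   remote-methoxy variant.
#' @export
build_fragment_library <- function(config = generator_config(),
                                   seed = config$seed) {
  pools <- cache_fetch("fragment_pools", function() {
    list(acids = enumerate_acid_pool(), amines = enumerate_amine_pool())
  })
  with_seed(seed * 7 + 11, {
    edit_map <- cliff_editable_acids()
    rest <- setdiff(pools$acids, names(edit_map))
    n_rest <- max(0, min(config$n_acids - length(edit_map), length(rest)))
    acids <- c(names(edit_map), sample(rest, n_rest))
    amines <- character(0); cls <- character(0)
    for (k in names(pools$amines)) {
      pick <- sample(pools$amines[[k]],
                     min(config$n_amines_per_class, length(pools$amines[[k]])))
      amines <- c(amines, pick)
      cls <- c(cls, rep(k, length(pick)))
    }
    list(acids = acids, amines = amines, amine_class = cls,
         cliff_edit = edit_map)
  })
}

# --- latent yield ------------------------------------------------------------

amine_steric_count <- function(smiles) {
  g <- parse_smiles(smiles)
  h <- heavy_view(g)
  site <- find_amine_sites(g)[1]
  hidx <- match(site, g$heavy)
  D <- heavy_distance_matrix(h)
  sum(D[hidx, ] <= 2) - 1
}

acid_ewg_count <- function(smiles) {
  g <- parse_smiles(smiles)
  h <- heavy_view(g)
  nitriles <- sum(h$elem == "N" & vapply(h$adj, function(m) {
    !is.null(m) && any(m[, 2] == 3)
  }, logical(1)))
  sum(h$elem %in% c("F", "Cl", "Br")) + nitriles
}

#' Yield-model coefficients
#'
#' The latent (noiseless) yield is a squashed linear model over interpretable
#' structure and context terms:
#' `z = intercept + class_offset(amine) + steric * (heavy atoms within two
#' bonds of the amine N) + ewg * (acid halogen/nitrile count) + size *
#' (acid heavy atoms) + sum(context label effects)`, mapped to (0, 100) by a
#' scaled logistic `y = 100 / (1 + exp(-(z - 50) / width))`.
#'
#' @param intercept Linear intercept (calibrated by the generator to hit the
#'   configured mean yield).
#' @param class_offsets Named offsets for the three amine classes.
#' @param steric,ewg,size Structure-term coefficients.
#' @param context_effects Named numeric vector of per-label effects.
#' @param squash_width Logistic width in yield points.
#' @return An object of class `yield_coefficients`.
#' @export
yield_coefficients <- function(intercept = 50,
                               class_offsets = c(primary_aliphatic = 7,
                                                 primary_aromatic = -9,
                                                 secondary = -2),
                               steric = -2.2, ewg = -3.6, size = -0.35,
                               context_effects = numeric(0),
                               squash_width = 16) {
  obj <- list(intercept = intercept, class_offsets = class_offsets,
              steric = steric, ewg = ewg, size = size,
              context_effects = context_effects, squash_width = squash_width)
  class(obj) <- "yield_coefficients"
  obj
}

squash_yield <- function(z, width) 100 / (1 + exp(-(z - 50) / width))

latent_structure_term <- function(acid_smiles, amine_smiles, coef) {
  key <- paste0("lat::", acid_smiles, "::", amine_smiles, "::",
                paste(signif(c(coef$class_offsets, coef$steric, coef$ewg,
                               coef$size), 10), collapse = ","))
  cache_fetch(key, function() {
    cls <- classify_amine(amine_smiles)
    n_heavy <- length(parse_smiles(acid_smiles)$heavy)
    coef$class_offsets[[cls]] +
      coef$steric * amine_steric_count(amine_smiles) +
      coef$ewg * acid_ewg_count(acid_smiles) +
      coef$size * n_heavy
  })
}

#' Latent (noiseless) yield of a reaction
#'
#' Deterministic function of the acid, the amine and the context under a
#' fixed coefficient set; remote substituents with zero coefficients do not
#' change it.
#'
#' @param acid,amine [molecule]s or SMILES strings.
#' @param context A [reaction_context].
#' @param coefficients A [yield_coefficients].
#' @return Latent yield in (0, 100).
#' @export
latent_yield <- function(acid, amine, context, coefficients) {
  acid_smi <- if (inherits(acid, "molecule")) acid$smiles else canonicalize(acid)
  amine_smi <- if (inherits(amine, "molecule")) amine$smiles else canonicalize(amine)
  ctx_effect <- sum(coefficients$context_effects[
    intersect(context_labels(context), names(coefficients$context_effects))])
  z <- coefficients$intercept +
    latent_structure_term(acid_smi, amine_smi, coefficients) + ctx_effect
  squash_yield(z, coefficients$squash_width)
}

# --- dataset generation ------------------------------------------------------

#' Generate a synthetic amide-coupling dataset with ground truth
#'
#' Emits `n_reactions` records with observed yield = clip(latent + Gaussian
#' noise); plants reactivity cliffs (a remote methoxy edit on the acid with a
#' forced observed gap, fingerprint+context cosine similarity kept above
#' 0.9), plants uncertain groups (exact duplicate reactions with distinct
#' yields drawn over the configured span), and assigns latent per-molecule
#' electronic energies calibrated so that corr(yield, dE_rxn) matches the
#' configured target. Every emitted record passes [validate_record()];
#' everything is deterministic under the configured seed.
#'
#' @param config A [generator_config].
#' @return A list of class `synthetic_reaction_data` with elements `dataset`
#'   (a [reaction_dataset]) and `truth` (planted cliff pairs, uncertain
#'   groups, latent yields, per-molecule energies, coefficients).
#' @export
generate_dataset <- function(config = generator_config()) {
  lib <- build_fragment_library(config)
  with_seed(config$seed * 13 + 101, {
    vocab_spec <- list(
      solvent = sprintf("solv%02d", seq_len(config$n_solvents)),
      reagent = sprintf("reag%02d", seq_len(config$n_reagents)),
      condition = sprintf("cond%02d", seq_len(config$n_conditions)))
    ctx_effects <- c(
      stats::setNames(stats::rnorm(config$n_solvents, 0, 6),
                      paste0("solvent:", vocab_spec$solvent)),
      stats::setNames(stats::rnorm(config$n_reagents, 0, 4),
                      paste0("reagent:", vocab_spec$reagent)),
      stats::setNames(stats::rnorm(config$n_conditions, 0, 3),
                      paste0("condition:", vocab_spec$condition)))
    coef <- yield_coefficients(context_effects = ctx_effects)

    n_extra <- config$n_planted_cliffs +
      config$n_planted_uncertain * (config$uncertain_group_size - 1)
    n_base <- config$n_reactions - n_extra

    draw_context <- function(n) {
      data.frame(
        solvent = sample(vocab_spec$solvent, n, replace = TRUE),
        reagent = sample(vocab_spec$reagent, n, replace = TRUE),
        condition = sample(vocab_spec$condition, n, replace = TRUE),
        temperature = round(stats::runif(n, 0, 80)),
        time = round(stats::runif(n, 0.5, 48), 1),
        stringsAsFactors = FALSE)
    }

    base <- data.frame(
      acid = sample(lib$acids, n_base, replace = TRUE),
      amine = sample(lib$amines, n_base, replace = TRUE),
      agent = sample(names(CARBODIIMIDES), n_base, replace = TRUE,
                     prob = c(0.6, 0.25, 0.15)),
      draw_context(n_base), stringsAsFactors = FALSE)

    # calibrate the intercept so the mean latent yield hits the target
    s_term <- mapply(latent_structure_term, base$acid, base$amine,
                     MoreArgs = list(coef = coef))
    ctx_term <- coef$context_effects[paste0("solvent:", base$solvent)] +
      coef$context_effects[paste0("reagent:", base$reagent)] +
      coef$context_effects[paste0("condition:", base$condition)]
    coef$intercept <- stats::uniroot(function(b0) {
      mean(squash_yield(b0 + s_term + ctx_term, coef$squash_width)) -
        config$mean_yield
    }, c(-200, 300))$root
    latent <- squash_yield(coef$intercept + s_term + ctx_term,
                           coef$squash_width)
    observed <- pmin(100, pmax(0, latent +
                                 stats::rnorm(n_base, 0, config$yield_noise_sd)))

    rows <- cbind(base, latent = latent, observed = observed,
                  planted = "base", stringsAsFactors = FALSE)

    # --- plant reactivity cliffs: remote methyl edit on an editable acid,
    # verified to stay above the similarity threshold in the cliff feature
    # space (acid + amine fingerprints plus the shared context slice)
    cliff_pairs <- NULL
    if (config$n_planted_cliffs > 0) {
      amine_heavy <- vapply(lib$amines, function(s) {
        length(parse_smiles(s)$heavy)
      }, numeric(1))
      big_amines <- lib$amines[amine_heavy >= 4]
      eligible <- which(rows$acid %in% names(lib$cliff_edit) &
                          rows$amine %in% big_amines)
      pair_sim_ok <- function(acid, edited, amine) {
        fa <- morgan_fingerprint(acid); fe <- morgan_fingerprint(edited)
        fm <- morgan_fingerprint(amine)
        v1 <- c(fa, fm, rep(1, 3)); v2 <- c(fe, fm, rep(1, 3))
        sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2)) > 0.9
      }
      eligible <- sample(eligible)
      picks <- integer(0)
      for (e in eligible) {
        if (length(picks) >= config$n_planted_cliffs) break
        if (pair_sim_ok(rows$acid[e], lib$cliff_edit[[rows$acid[e]]],
                        rows$amine[e])) {
          picks <- c(picks, e)
        }
      }
      if (length(picks) < config$n_planted_cliffs) {
        stop("could not plant ", config$n_planted_cliffs,
             " similarity-verified cliffs (", length(picks), " feasible)")
      }
      partner <- rows[picks, , drop = FALSE]
      partner$acid <- unname(lib$cliff_edit[partner$acid])
      partner$latent <- mapply(function(a, m, sv, rg, cd) {
        z <- coef$intercept + latent_structure_term(a, m, coef) +
          coef$context_effects[[paste0("solvent:", sv)]] +
          coef$context_effects[[paste0("reagent:", rg)]] +
          coef$context_effects[[paste0("condition:", cd)]]
        squash_yield(z, coef$squash_width)
      }, partner$acid, partner$amine, partner$solvent, partner$reagent,
         partner$condition)
      gap <- config$cliff_gap + stats::runif(config$n_planted_cliffs, 0.5, 5)
      down <- rows$observed[picks] >= gap + 2
      partner$observed <- ifelse(down,
                                 pmax(0, rows$observed[picks] - gap),
                                 pmin(100, rows$observed[picks] + gap))
      partner$planted <- "cliff_partner"
      rows$planted[picks] <- "cliff_base"
      rows <- rbind(rows, partner)
      cliff_pairs <- data.frame(base_row = picks,
                                partner_row = n_base + seq_len(nrow(partner)))
    }

    # --- plant uncertain groups: exact duplicates with spread-out yields
    uncertain_groups <- list()
    if (config$n_planted_uncertain > 0) {
      avail <- which(rows$planted == "base")
      picks_u <- sample(avail, config$n_planted_uncertain)
      extra <- NULL
      for (gi in seq_along(picks_u)) {
        p <- picks_u[gi]
        k <- config$uncertain_group_size
        ys <- stats::runif(k, config$uncertain_span[1], config$uncertain_span[2])
        while (length(unique(round(ys, 6))) < k) {
          ys <- stats::runif(k, config$uncertain_span[1], config$uncertain_span[2])
        }
        rows$observed[p] <- ys[1]
        rows$planted[p] <- "uncertain"
        dup <- rows[rep(p, k - 1), , drop = FALSE]
        dup$observed <- ys[-1]
        start <- nrow(rows) + (if (is.null(extra)) 0 else nrow(extra))
        uncertain_groups[[gi]] <- c(p, start + seq_len(k - 1))
        extra <- rbind(extra, dup)
      }
      rows <- rbind(rows, extra)
    }

    rownames(rows) <- NULL
    ids <- sprintf("RXN%05d", seq_len(nrow(rows)))

    # products for all unique pairs in one batched conversion
    prod_smiles <- condense_products_batch(rows$acid, rows$amine)

    # --- latent electronic energies calibrated to the target correlation
    e_water <- -76.4
    uniq_mol <- unique(c(rows$acid, rows$amine))
    e_mol <- stats::setNames(
      -40 * vapply(uniq_mol, function(s) length(parse_smiles(s)$heavy),
                   numeric(1)) + stats::rnorm(length(uniq_mol), 0, 2),
      uniq_mol)
    pair_key <- paste(rows$acid, rows$amine)
    uniq_pair <- !duplicated(pair_key)
    s_all <- mapply(latent_structure_term, rows$acid, rows$amine,
                    MoreArgs = list(coef = coef))
    s_std <- as.numeric(scale(s_all))
    eps_pair <- stats::setNames(stats::rnorm(sum(uniq_pair)),
                                pair_key[uniq_pair])
    rho_ys <- stats::cor(rows$observed, s_std)
    cmix <- max(-1, min(1, abs(config$target_de_corr) / rho_ys))
    delta <- 5 * (-cmix * s_std + sqrt(max(0, 1 - cmix^2)) *
                    eps_pair[pair_key]) - 10
    e_prod <- stats::setNames(
      e_mol[rows$acid] + e_mol[rows$amine] - e_water + delta,
      prod_smiles)[!duplicated(prod_smiles)]
    energies <- c(e_mol, e_prod, stats::setNames(e_water, canonicalize("O")))

    records <- lapply(seq_len(nrow(rows)), function(i) {
      reaction_record(
        reaction_id = ids[i],
        acid = molecule(rows$acid[i], "acid"),
        amine = molecule(rows$amine[i], "amine"),
        product = molecule(prod_smiles[i], "product"),
        coupling_agent = rows$agent[i],
        yield_percent = round(rows$observed[i], 4),
        context = reaction_context(
          reagents = rows$reagent[i], solvents = rows$solvent[i],
          temperature = rows$temperature[i], time = rows$time[i],
          conditions = rows$condition[i]))
    })
    vocab <- context_vocabulary(sort(c(
      paste0("solvent:", vocab_spec$solvent),
      paste0("reagent:", vocab_spec$reagent),
      paste0("condition:", vocab_spec$condition))))
    dataset <- reaction_dataset(records, vocab)

    truth <- list(
      cliff_pairs = if (is.null(cliff_pairs)) {
        data.frame(id_a = character(0), id_b = character(0))
      } else {
        data.frame(id_a = ids[cliff_pairs$base_row],
                   id_b = ids[cliff_pairs$partner_row],
                   stringsAsFactors = FALSE)
      },
      uncertain_groups = lapply(uncertain_groups, function(ix) ids[ix]),
      latent_yield = stats::setNames(rows$latent, ids),
      energies = energies,
      coefficients = coef,
      planted = stats::setNames(rows$planted, ids))
    out <- list(dataset = dataset, truth = truth, config = config)
    class(out) <- "synthetic_reaction_data"
    out
  })
}

#' Oracle QM provider backed by generator ground truth
#'
#' Returns the generator's latent electronic energies exactly; the remaining
#' fields fall back to the heuristic provider's deterministic values.
#'
#' @param truth The `truth` element of [generate_dataset()] output.
#' @return A provider function compatible with [qm_features()].
#' @export
oracle_qm_provider <- function(truth) {
  heur <- heuristic_qm_provider()
  f <- function(smiles) {
    smiles <- canonicalize(smiles)
    rec <- heur(smiles)
    if (!smiles %in% names(truth$energies)) {
      stop("molecule absent from oracle energy table: ", smiles)
    }
    rec$energy <- unname(truth$energies[[smiles]])
    rec$provider <- "oracle"
    rec
  }
  attr(f, "name") <- "oracle"
  # energy-only fast path; species outside the generator's table (e.g.
  # O-acylisourea intermediates) fall back to the heuristic surrogate
  attr(f, "energy_fun") <- function(smiles) {
    smiles <- canonicalize(smiles)
    if (smiles %in% names(truth$energies)) {
      unname(truth$energies[[smiles]])
    } else {
      heur(smiles)$energy
    }
  }
  f
}
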