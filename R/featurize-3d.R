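# Geometry-derived descriptors: seeded distance-geometry conformer embedding,
# atomic environment vectors (radial/angular symmetry functions) with
# sum-pooling, percent-buried-volume sterics, and surrogate QM reaction
# features including the electronic reaction energy.

BONDI_VDW <- c(H = 1.20, B = 1.92, C = 1.70, N = 1.55, O = 1.52, F = 1.47,
               Si = 2.10, P = 1.80, S = 1.80, Cl = 1.75, Br = 1.85, I = 1.98)

# Reference bond lengths (Angstrom) by element pair and order; pairs not
# listed fall back to the sum of covalent radii (minus 0.12/0.22 for double
# and triple bonds).
bond_length_ref <- function(e1, e2, order) {
  key <- paste(sort(c(e1, e2)), collapse = "-")
  tab1 <- c("C-C" = 1.54, "C-H" = 1.09, "C-N" = 1.47, "C-O" = 1.43,
            "H-N" = 1.01, "H-O" = 0.96, "C-S" = 1.81, "C-F" = 1.35,
            "C-Cl" = 1.77, "N-N" = 1.45, "N-O" = 1.40, "O-S" = 1.57,
            "H-S" = 1.34, "C-Br" = 1.94, "C-I" = 2.14, "C-Si" = 1.85,
            "C-P" = 1.84)
  tab2 <- c("C-C" = 1.34, "C-N" = 1.28, "C-O" = 1.21, "N-N" = 1.25,
            "N-O" = 1.21, "O-S" = 1.45, "C-S" = 1.60)
  tab3 <- c("C-C" = 1.20, "C-N" = 1.16)
  val <- switch(order, tab1[key], tab2[key], tab3[key])
  if (!is.null(val) && !is.na(val)) return(unname(val))
  base <- COVALENT_RADIUS[[e1]] + COVALENT_RADIUS[[e2]]
  base - c(0, 0.12, 0.22)[min(order, 3)]
}

# deterministic linear-congruential stream, avoids touching R's global RNG
lcg_runif <- function(n, seed) {
  state <- (as.numeric(seed) %% 2147483647) + 1
  out <- numeric(n)
  for (i in seq_len(n)) {
    state <- (state * 48271) %% 2147483647
    out[i] <- state / 2147483647
  }
  out
}

#' Embed a molecule into a single low-energy 3D conformer
#'
#' Distance-geometry style embedding: harmonic restraints on bonded (1-2)
#' distances and angle-derived (1-3) distances plus a soft nonbonded
#' repulsion are minimized with BFGS from `k` seeded random starts; the
#' lowest-objective geometry is returned and its final objective value is
#' stored as the surrogate energy. Deterministic for a fixed seed.
#'
#' @param mol A [molecule] or SMILES string (single connected component).
#' @param seed Integer seed.
#' @param k Number of seeded restarts (best kept).
#' @param max_atoms Guard on molecule size.
#' @return A [conformer3d].
#' @export
embed_conformer <- function(mol, seed = 1L, k = 10L, max_atoms = 200L) {
  smiles <- if (inherits(mol, "molecule")) mol$smiles else canonicalize(mol)
  key <- paste0("conf::", smiles, "::", seed, "::", k)
  cache_fetch(key, function() {
    g <- parse_smiles(smiles)
    if (g$n > max_atoms) stop("molecule exceeds atom limit: ", smiles)
    if (n_components(heavy_view(g)) > 1 && length(g$heavy) > 1) {
      stop("disconnected molecule cannot be embedded: ", smiles)
    }
    restraints <- embedding_restraints(g)
    best <- NULL
    for (trial in seq_len(k)) {
      x0 <- matrix(4 * (lcg_runif(3 * g$n, seed * 1000 + trial) - 0.5) *
                     max(2, g$n^(1 / 3)), ncol = 3)
      fit <- stats::optim(as.vector(x0), fn = dg_objective, gr = dg_gradient,
                          restraints = restraints, n = g$n, method = "BFGS",
                          control = list(maxit = 400, reltol = 1e-10))
      if (is.null(best) || fit$value < best$value) best <- fit
    }
    conformer3d(g$elem, matrix(best$par, ncol = 3), energy = best$value,
                net_charge = sum(g$charge))
  })
}

embedding_restraints <- function(g) {
  rows <- list()
  add <- function(i, j, d0, w, repulsive) {
    rows[[length(rows) + 1]] <<- c(i, j, d0, w, repulsive)
  }
  nbonds <- nrow(g$bonds)
  for (b in seq_len(nbonds)) {
    i <- g$bonds[b, 1]; j <- g$bonds[b, 2]
    add(i, j, bond_length_ref(g$elem[i], g$elem[j], g$bonds[b, 3]), 50, 0)
  }
  # 1-3 distances from idealized angles at the central atom
  for (jc in seq_len(g$n)) {
    nb <- g$adj[[jc]]
    if (is.null(nb) || nrow(nb) < 2) next
    ang <- central_angle(g, jc)
    for (a in seq_len(nrow(nb) - 1)) {
      for (b2 in (a + 1):nrow(nb)) {
        i <- nb[a, 1]; k2 <- nb[b2, 1]
        d1 <- bond_length_ref(g$elem[i], g$elem[jc], nb[a, 2])
        d2 <- bond_length_ref(g$elem[k2], g$elem[jc], nb[b2, 2])
        d13 <- sqrt(d1^2 + d2^2 - 2 * d1 * d2 * cos(ang))
        add(i, k2, d13, 15, 0)
      }
    }
  }
  # soft repulsion between all other pairs
  bonded <- paste(pmin(g$bonds[, 1], g$bonds[, 2]),
                  pmax(g$bonds[, 1], g$bonds[, 2]))
  onethree <- character(0)
  for (jc in seq_len(g$n)) {
    nb <- g$adj[[jc]]
    if (is.null(nb) || nrow(nb) < 2) next
    cmb <- utils::combn(sort(nb[, 1]), 2)
    onethree <- c(onethree, paste(cmb[1, ], cmb[2, ]))
  }
  excluded <- union(bonded, onethree)
  for (i in seq_len(g$n - 1)) {
    for (j in (i + 1):g$n) {
      if (paste(i, j) %in% excluded) next
      dmin <- 0.75 * (BONDI_VDW[[g$elem[i]]] + BONDI_VDW[[g$elem[j]]])
      add(i, j, dmin, 4, 1)
    }
  }
  do.call(rbind, rows)
}

central_angle <- function(g, jc) {
  nb <- g$adj[[jc]]
  orders <- nb[, 2]
  heavy_deg <- nrow(nb)
  if (any(orders == 3) || sum(orders == 2) >= 2) return(pi)
  if (any(orders == 2) || (g$ring_atom[jc] && is_aromatic_carbon(g, jc))) {
    return(2 * pi / 3)
  }
  if (heavy_deg == 2 && g$elem[jc] == "O") return(104.5 * pi / 180)
  acos(-1 / 3)  # tetrahedral
}

dg_objective <- function(x, restraints, n) {
  p <- matrix(x, ncol = 3)
  d <- sqrt(rowSums((p[restraints[, 1], , drop = FALSE] -
                     p[restraints[, 2], , drop = FALSE])^2) + 1e-12)
  diff <- d - restraints[, 3]
  rep_mask <- restraints[, 5] == 1
  harm <- sum(restraints[!rep_mask, 4] * diff[!rep_mask]^2)
  viol <- pmin(diff[rep_mask], 0)
  harm + sum(restraints[rep_mask, 4] * viol^2)
}

dg_gradient <- function(x, restraints, n) {
  p <- matrix(x, ncol = 3)
  v <- p[restraints[, 1], , drop = FALSE] - p[restraints[, 2], , drop = FALSE]
  d <- sqrt(rowSums(v^2) + 1e-12)
  diff <- d - restraints[, 3]
  coef <- 2 * restraints[, 4] * diff
  coef[restraints[, 5] == 1 & diff >= 0] <- 0
  gpair <- v * (coef / d)
  grad <- matrix(0, n, 3)
  s1 <- rowsum(gpair, restraints[, 1])
  grad[as.integer(rownames(s1)), ] <- s1
  i2 <- as.integer(rownames(s2 <- rowsum(gpair, restraints[, 2])))
  grad[i2, ] <- grad[i2, ] - s2
  as.vector(grad)
}

# --- atomic environment vectors ---------------------------------------------

#' AEV symmetry-function parameters
#'
#' Standard radial/angular symmetry-function preset: radial cutoff 5.2 A with
#' 16 shells, angular cutoff 3.5 A with 4 radial x 8 angle sections,
#' Gaussian widths eta, angular sharpness zeta, and one element channel per
#' supported species.
#'
#' @param radial_cutoff,radial_shells,radial_eta Radial term parameters.
#' @param angular_cutoff,angular_shells,angular_eta Angular radial part.
#' @param angle_sections Number of angle centers spread over `[0, pi]`.
#' @param zeta Angular sharpness.
#' @param channels Element symbols covered.
#' @return An object of class `aev_params`.
#' @export
aev_params <- function(radial_cutoff = 5.2, radial_shells = 16,
                       radial_eta = 16, angular_cutoff = 3.5,
                       angular_shells = 4, angular_eta = 8,
                       angle_sections = 8, zeta = 32,
                       channels = c("H", "C", "N", "O", "F", "Si", "P", "S", "Cl")) {
  stopifnot(radial_cutoff > 0, angular_cutoff > 0, radial_shells >= 1,
            angular_shells >= 1, angle_sections >= 1)
  rs <- seq(0.9, radial_cutoff, length.out = radial_shells + 1)[1:radial_shells]
  ra <- seq(0.9, angular_cutoff, length.out = angular_shells + 1)[1:angular_shells]
  th <- (seq_len(angle_sections) - 0.5) * pi / angle_sections
  obj <- list(radial_cutoff = radial_cutoff, radial_rs = rs,
              radial_eta = radial_eta, angular_cutoff = angular_cutoff,
              angular_rs = ra, angular_eta = angular_eta, theta_s = th,
              zeta = zeta, channels = channels)
  class(obj) <- "aev_params"
  obj
}

#' @rdname aev_params
#' @export
aev_params_default <- function() aev_params()

fc_cutoff <- function(r, rc) ifelse(r < rc, 0.5 * cos(pi * r / rc) + 0.5, 0)

#' Compute per-atom atomic environment vectors
#'
#' For each atom, radial terms `G = sum_j exp(-eta (R_ij - Rs)^2) fc(R_ij)`
#' per element channel and ANI-style angular terms over neighbor pairs, with
#' the smooth cosine cutoff `fc(R) = 0.5 cos(pi R / Rc) + 0.5` for `R < Rc`.
#' The result is invariant to rigid rotation/translation and to permutation
#' of identical atoms.
#'
#' @param conf A [conformer3d].
#' @param params An [aev_params].
#' @return Numeric matrix, one row per atom, with named feature columns.
#' @export
compute_aev <- function(conf, params = aev_params_default()) {
  sp <- conf$species
  missing_ch <- setdiff(unique(sp), params$channels)
  if (length(missing_ch) > 0) {
    stop("species missing from AEV channel list: ",
         paste(missing_ch, collapse = ", "))
  }
  n <- length(sp)
  ch <- params$channels
  nch <- length(ch)
  pair_idx <- which(upper.tri(matrix(0, nch, nch)), arr.ind = TRUE)
  pairs_ch <- rbind(cbind(seq_len(nch), seq_len(nch)), pair_idx)  # e1 <= e2
  pairs_ch <- pairs_ch[order(pairs_ch[, 1], pairs_ch[, 2]), , drop = FALSE]
  nrad <- length(params$radial_rs)
  nang_r <- length(params$angular_rs)
  nth <- length(params$theta_s)
  rad_names <- as.vector(outer(seq_len(nrad), ch,
                               function(s, e) paste0("rad_", e, "_", s)))
  ang_names <- as.vector(sapply(seq_len(nrow(pairs_ch)), function(pk) {
    e1 <- ch[pairs_ch[pk, 1]]; e2 <- ch[pairs_ch[pk, 2]]
    as.vector(outer(seq_len(nth), seq_len(nang_r), function(t, s) {
      paste0("ang_", e1, e2, "_", s, "_", t)
    }))
  }))
  width <- nch * nrad + nrow(pairs_ch) * nang_r * nth
  out <- matrix(0, n, width)
  colnames(out) <- c(rad_names, ang_names)
  if (n == 1) return(out)

  dmat <- as.matrix(stats::dist(conf$coords))
  ch_of <- match(sp, ch)
  for (i in seq_len(n)) {
    # radial
    nbr <- which(dmat[i, ] < params$radial_cutoff & seq_len(n) != i)
    if (length(nbr) > 0) {
      fcv <- fc_cutoff(dmat[i, nbr], params$radial_cutoff)
      for (e in seq_len(nch)) {
        js <- nbr[ch_of[nbr] == e]
        if (length(js) == 0) next
        r <- dmat[i, js]
        fcr <- fc_cutoff(r, params$radial_cutoff)
        gvals <- vapply(params$radial_rs, function(rs) {
          sum(exp(-params$radial_eta * (r - rs)^2) * fcr)
        }, numeric(1))
        out[i, ((e - 1) * nrad + 1):(e * nrad)] <- gvals
      }
    }
    # angular
    nbra <- which(dmat[i, ] < params$angular_cutoff & seq_len(n) != i)
    if (length(nbra) >= 2) {
      cmb <- utils::combn(nbra, 2)
      for (cidx in seq_len(ncol(cmb))) {
        j <- cmb[1, cidx]; k2 <- cmb[2, cidx]
        rij <- dmat[i, j]; rik <- dmat[i, k2]
        vj <- conf$coords[j, ] - conf$coords[i, ]
        vk <- conf$coords[k2, ] - conf$coords[i, ]
        cth <- sum(vj * vk) / (rij * rik)
        cth <- max(-1, min(1, cth))
        theta <- acos(0.95 * cth)
        e1 <- min(ch_of[j], ch_of[k2]); e2 <- max(ch_of[j], ch_of[k2])
        pk <- which(pairs_ch[, 1] == e1 & pairs_ch[, 2] == e2)
        fcp <- fc_cutoff(rij, params$angular_cutoff) *
               fc_cutoff(rik, params$angular_cutoff)
        ravg <- (rij + rik) / 2
        base_col <- nch * nrad + (pk - 1) * nang_r * nth
        for (s in seq_len(nang_r)) {
          radial_part <- exp(-params$angular_eta *
                               (ravg - params$angular_rs[s])^2)
          ang_part <- 2^(1 - params$zeta) *
            (1 + cos(theta - params$theta_s))^params$zeta
          cols <- base_col + (s - 1) * nth + seq_len(nth)
          out[i, cols] <- out[i, cols] + ang_part * radial_part * fcp
        }
      }
    }
  }
  out
}

#' Sum-pool per-atom AEVs into a molecular vector
#'
#' @param per_atom Matrix of per-atom AEVs (rows = atoms).
#' @return Named numeric vector (element-wise sum over atoms).
#' @export
pool_aev <- function(per_atom) {
  if (is.null(dim(per_atom)) || nrow(per_atom) == 0) {
    stop("pool_aev needs at least one atom row")
  }
  colSums(per_atom)
}

# --- buried volume -----------------------------------------------------------

#' Steric (buried volume) parameters
#'
#' @param probe_radius Probe sphere radius in Angstrom (default 3.5).
#' @param grid_spacing Grid step in Angstrom (default 0.1; must be smaller
#'   than the probe radius).
#' @param include_h Count hydrogen atoms as occluders.
#' @param vdw Named van der Waals radius table (Bondi).
#' @return An object of class `steric_params`.
#' @export
steric_params <- function(probe_radius = 3.5, grid_spacing = 0.1,
                          include_h = TRUE, vdw = BONDI_VDW) {
  if (grid_spacing >= probe_radius) {
    stop("grid spacing must be smaller than the probe radius")
  }
  obj <- list(probe_radius = probe_radius, grid_spacing = grid_spacing,
              include_h = include_h, vdw = vdw)
  class(obj) <- "steric_params"
  obj
}

#' @rdname steric_params
#' @export
steric_params_default <- function() steric_params()

#' Percent buried volume around an atom
#'
#' Fraction (x100) of grid points within the probe sphere centered on
#' `center_atom` that fall inside the van der Waals sphere of any atom of the
#' conformer.
#'
#' @param conf A [conformer3d].
#' @param center_atom Atom index (1-based) of the sphere center.
#' @param params A [steric_params].
#' @return Percentage in `[0, 100]`.
#' @export
buried_volume <- function(conf, center_atom, params = steric_params_default()) {
  n <- length(conf$species)
  if (center_atom < 1 || center_atom > n) stop("center_atom out of range")
  no_radius <- setdiff(unique(conf$species), names(params$vdw))
  if (length(no_radius) > 0) {
    stop("no vdW radius for species: ", paste(no_radius, collapse = ", "))
  }
  ctr <- conf$coords[center_atom, ]
  R <- params$probe_radius
  ax <- seq(-R, R, by = params$grid_spacing)
  grid <- as.matrix(expand.grid(x = ax, y = ax, z = ax))
  inside_probe <- rowSums(grid^2) <= R^2
  grid <- grid[inside_probe, , drop = FALSE]
  pts <- sweep(grid, 2, ctr, `+`)
  keep_atoms <- seq_len(n)
  if (!params$include_h) keep_atoms <- which(conf$species != "H")
  buried <- rep(FALSE, nrow(pts))
  for (a in keep_atoms) {
    ra <- params$vdw[[conf$species[a]]]
    da <- sqrt(rowSums(sweep(pts, 2, conf$coords[a, ], `-`)^2))
    # skip atoms that cannot intersect the probe sphere
    if (sqrt(sum((conf$coords[a, ] - ctr)^2)) > R + ra) next
    buried <- buried | (da <= ra)
  }
  100 * mean(buried)
}

# --- surrogate QM ------------------------------------------------------------

QM_ELEMENTS <- c("H", "C", "N", "O", "F", "Si", "P", "S", "Cl")

#' Construct a QM record
#'
#' @param smiles Canonical SMILES the record describes.
#' @param energy Electronic energy (provider units).
#' @param charges,fukui_plus,fukui_minus Per-atom numeric vectors aligned to
#'   the canonical atom order (explicit hydrogens included).
#' @param ip,ea Ionization potential and electron affinity.
#' @param provider Provider name (records from different providers must not
#'   be mixed in derived quantities).
#' @return An object of class `qm_record`.
#' @export
qm_record <- function(smiles, energy, charges, fukui_plus, fukui_minus, ip, ea,
                      provider = "unknown") {
  stopifnot(length(charges) == length(fukui_plus),
            length(charges) == length(fukui_minus), is.finite(energy))
  obj <- list(smiles = smiles, energy = energy, charges = charges,
              fukui_plus = fukui_plus, fukui_minus = fukui_minus,
              ip = ip, ea = ea, provider = provider)
  class(obj) <- "qm_record"
  obj
}

#' Heuristic surrogate QM provider
#'
#' A deterministic additive group-contribution stand-in for a quantum
#' chemistry engine: atomic base energies plus bond-order corrections give
#' the electronic energy; partial charges follow electronegativity
#' differences along bonds; Fukui indices are normalized reactivity scores
#' emphasizing carbonyl carbons (electrophilic) and amine nitrogens
#' (nucleophilic). Supports the element set H, C, N, O, F, Si, P, S, Cl and
#' raises a coverage error otherwise.
#'
#' @return A provider function `f(smiles) -> qm_record`.
#' @export
heuristic_qm_provider <- function() {
  base_e <- c(H = -0.50, C = -37.8, N = -54.6, O = -75.0, F = -99.7,
              Si = -289.4, P = -341.3, S = -398.1, Cl = -460.1)
  f <- function(smiles) {
    smiles <- canonicalize(smiles)
    cache_fetch(paste0("qm::heuristic::", smiles), function() {
      g <- parse_smiles(smiles)
      bad <- setdiff(unique(g$elem), QM_ELEMENTS)
      if (length(bad) > 0) {
        stop("element(s) outside provider coverage: ", paste(bad, collapse = ", "))
      }
      bond_corr <- sum(-0.05 * g$bonds[, 3])
      energy <- sum(base_e[g$elem]) + bond_corr
      charges <- numeric(g$n)
      for (b in seq_len(nrow(g$bonds))) {
        i <- g$bonds[b, 1]; j <- g$bonds[b, 2]
        dq <- 0.16 * (PAULING_EN[[g$elem[j]]] - PAULING_EN[[g$elem[i]]])
        charges[i] <- charges[i] + dq
        charges[j] <- charges[j] - dq
      }
      # electrophilic susceptibility: high for carbons bonded to =O
      fplus <- vapply(seq_len(g$n), function(i) {
        if (g$elem[i] != "C") return(0.02)
        nb <- g$adj[[i]]
        if (!is.null(nb) && any(nb[, 2] == 2 & g$elem[nb[, 1]] == "O")) 0.6 else 0.05
      }, numeric(1))
      # nucleophilic susceptibility: amine N, attenuated by local crowding
      h <- heavy_view(g)
      D <- if (h$n >= 2) heavy_distance_matrix(h) else matrix(0, 1, 1)
      fminus <- vapply(seq_len(g$n), function(i) {
        if (g$elem[i] == "N" && g$hcount[i] > 0) {
          hi <- match(i, g$heavy)
          crowd <- sum(D[hi, ] <= 2) - 1
          max(0.05, 0.5 - 0.04 * crowd)
        } else if (g$elem[i] %in% c("N", "O")) 0.2
        else 0.02
      }, numeric(1))
      ip <- 9 + 0.5 * mean(PAULING_EN[g$elem]) - 0.02 * sum(g$elem != "H")
      ea <- -0.5 + 0.08 * sum(g$elem %in% c("O", "N", "F", "Cl"))
      qm_record(smiles, energy, charges, fplus, fminus, ip, ea, "heuristic")
    })
  }
  attr(f, "name") <- "heuristic"
  f
}

#' Surrogate QM features for a molecule
#'
#' @param mol A [molecule] or SMILES string.
#' @param provider A provider function, e.g. [heuristic_qm_provider()].
#' @return A [qm_record].
#' @export
qm_features <- function(mol, provider = heuristic_qm_provider()) {
  smiles <- if (inherits(mol, "molecule")) mol$smiles else canonicalize(mol)
  provider(smiles)
}

#' Electronic reaction energy
#'
#' `dE_rxn = E(product) + E(water) - E(acid) - E(amine)`, all energies from
#' the same provider.
#'
#' @param e_product,e_water,e_acid,e_amine Electronic energies.
#' @return The electronic reaction energy.
#' @examples
#' delta_e_rxn(-100, -76, -120, -55)  # -1
#' @export
delta_e_rxn <- function(e_product, e_water, e_acid, e_amine) {
  e_product + e_water - e_acid - e_amine
}

#' Derive reaction-level QM features
#'
#' Combines per-molecule QM records into a named reaction feature vector:
#' the electronic reaction energy, the Fukui difference
#' `df_rxn = f+(acid carboxyl C) - f-(amine N)`, center charges, per-reactant
#' ionization potentials and electron affinities, and molecular energies
#' (including the O-acylisourea when present; `NA` otherwise).
#'
#' @param acid_qm,amine_qm,product_qm [qm_record]s for the reactants/product.
#' @param water_qm [qm_record] for water (same provider).
#' @param centers A `reaction_centers` annotation for the triple.
#' @param intermediate_qm Optional [qm_record] for the O-acylisourea.
#' @return Named numeric vector (fixed schema).
#' @export
derive_reaction_qm <- function(acid_qm, amine_qm, product_qm, water_qm,
                               centers, intermediate_qm = NULL) {
  providers <- unique(c(acid_qm$provider, amine_qm$provider,
                        product_qm$provider, water_qm$provider))
  if (length(providers) > 1) {
    stop("QM records from mixed providers: ", paste(providers, collapse = ", "))
  }
  ga <- parse_smiles(acid_qm$smiles)
  acid_c <- centers$acid_atoms[ga$elem[centers$acid_atoms] == "C"][1]
  amine_n <- centers$amine_atoms[1]
  if (is.na(acid_c) || is.na(amine_n)) stop("missing center annotation")
  de <- delta_e_rxn(product_qm$energy, water_qm$energy, acid_qm$energy,
                    amine_qm$energy)
  mol_stats <- function(qm, tag) {
    stats::setNames(
      c(min(qm$charges), max(qm$charges), mean(qm$charges),
        min(qm$fukui_minus), max(qm$fukui_minus), mean(qm$fukui_minus),
        max(qm$fukui_plus), mean(qm$fukui_plus)),
      paste0(c("q_min_", "q_max_", "q_mean_", "f_minus_min_", "f_minus_max_",
               "f_minus_mean_", "f_plus_max_", "f_plus_mean_"), tag))
  }
  c(dE_rxn = de,
    df_rxn = acid_qm$fukui_plus[acid_c] - amine_qm$fukui_minus[amine_n],
    q_acid_c = acid_qm$charges[acid_c],
    q_amine_n = amine_qm$charges[amine_n],
    f_plus_acid_c = acid_qm$fukui_plus[acid_c],
    f_minus_amine_n = amine_qm$fukui_minus[amine_n],
    ip_acid = acid_qm$ip, ea_acid = acid_qm$ea,
    ip_amine = amine_qm$ip, ea_amine = amine_qm$ea,
    e_acid = acid_qm$energy, e_amine = amine_qm$energy,
    e_product = product_qm$energy,
    mol_stats(acid_qm, "acid"), mol_stats(amine_qm, "amine"),
    e_intermediate = if (is.null(intermediate_qm)) NA_real_ else intermediate_qm$energy)
}

# Reaction-level QM block for assemble_reaction_features. Reaction centers
# on the reactant side (acid carboxyl carbon, amine nitrogen) are located
# directly on the cached reactant graphs, and the product contributes only
# its energy, so the block costs one provider call per unique molecule.
qm_block_matrix <- function(dataset, options) {
  provider <- options$qm_provider
  pname <- attr(provider, "name") %||% "provider"
  water <- provider("O")
  reactant_centers <- function(acid_smi, amine_smi) {
    ga <- parse_smiles(acid_smi); gm <- parse_smiles(amine_smi)
    cg <- find_carboxyl_groups(ga)
    if (length(cg) == 0) stop("no carboxyl group in ", acid_smi)
    sites <- find_amine_sites(gm)
    if (length(sites) == 0) stop("no amine site in ", amine_smi)
    structure(list(acid_atoms = c(cg[[1]]$c, cg[[1]]$o_hydroxyl),
                   amine_atoms = sites[1]), class = "reaction_centers")
  }
  energy_of <- attr(provider, "energy_fun") %||% function(s) provider(s)$energy
  energy_stub <- function(smiles) {
    qm_record(smiles, energy_of(smiles), numeric(0), numeric(0), numeric(0),
              NA_real_, NA_real_, provider = pname)
  }
  rows <- lapply(dataset$records, function(r) {
    key <- paste0("qmrow::", pname, "::", r$acid$smiles, "::", r$amine$smiles,
                  "::", r$product$smiles, "::",
                  if (is.null(r$intermediate)) "" else r$intermediate$smiles)
    cache_fetch(key, function() {
      inter_qm <- if (!is.null(r$intermediate)) energy_stub(r$intermediate$smiles)
      tryCatch(
        derive_reaction_qm(provider(r$acid$smiles), provider(r$amine$smiles),
                           energy_stub(r$product$smiles), water,
                           reactant_centers(r$acid$smiles, r$amine$smiles),
                           inter_qm),
        error = function(e) stop("QM featurization failed for ",
                                 r$reaction_id, ": ", conditionMessage(e)))
    })
  })
  m <- do.call(rbind, rows)
  colnames(m) <- paste0("qm_", colnames(m))
  m
}

# reaction-level steric block: buried volume at the acid carboxyl carbon and
# the amine nitrogen, computed on embedded conformers
steric_block_matrix <- function(dataset, options) {
  one_mol <- function(smiles, center_kind) {
    key <- paste0("vbur::", smiles, "::", center_kind, "::",
                  options$steric_params$probe_radius, "::",
                  options$steric_params$grid_spacing)
    cache_fetch(key, function() {
      g <- parse_smiles(smiles)
      idx <- if (center_kind == "acid_c") {
        cg <- find_carboxyl_groups(g)
        if (length(cg) == 0) stop("no carboxyl group in ", smiles)
        cg[[1]]$c
      } else {
        sites <- find_amine_sites(g)
        if (length(sites) == 0) stop("no amine site in ", smiles)
        sites[1]
      }
      conf <- embed_conformer(smiles, seed = options$embed_seed,
                              k = options$embed_k)
      buried_volume(conf, idx, options$steric_params)
    })
  }
  m <- t(vapply(dataset$records, function(r) {
    c(vbur_acid_c = one_mol(r$acid$smiles, "acid_c"),
      vbur_amine_n = one_mol(r$amine$smiles, "amine_n"))
  }, numeric(2)))
  m
}
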