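# Mechanism-derived augmentation for carbodiimide-mediated amide couplings:
# reactive-site perception, amide condensation, O-acylisourea intermediate
# construction, and reaction-center annotation.

# Find carboxylic acid groups: carbon with one =O and one -O-H neighbor.
# Returns a list of lists (c = carboxyl C, o_carbonyl, o_hydroxyl, h).
find_carboxyl_groups <- function(g) {
  out <- list()
  for (c_idx in which(g$elem == "C")) {
    nb <- g$adj[[c_idx]]
    if (is.null(nb)) next
    o_dbl <- nb[nb[, 2] == 2 & g$elem[nb[, 1]] == "O", 1]
    o_sgl <- nb[nb[, 2] == 1 & g$elem[nb[, 1]] == "O", 1]
    if (length(o_dbl) != 1 || length(o_sgl) < 1) next
    for (o_idx in o_sgl) {
      onb <- g$adj[[o_idx]]
      h <- onb[g$elem[onb[, 1]] == "H", 1]
      heavy_nb <- onb[g$elem[onb[, 1]] != "H", 1]
      if (length(h) == 1 && length(heavy_nb) == 1) {
        out[[length(out) + 1]] <- list(c = c_idx, o_carbonyl = o_dbl,
                                       o_hydroxyl = o_idx, h = h[1])
      }
    }
  }
  out
}

# Find reactive amine nitrogens: N with >= 1 H, neutral, all heavy neighbors
# carbon, and not an amide/anilide N (no neighboring carbonyl carbon).
find_amine_sites <- function(g) {
  out <- integer(0)
  for (n_idx in which(g$elem == "N")) {
    if (g$charge[n_idx] != 0L) next
    nb <- g$adj[[n_idx]]
    if (is.null(nb)) next
    if (any(nb[, 2] > 1)) next                     # imines, nitriles, diimides
    heavy <- nb[g$elem[nb[, 1]] != "H", , drop = FALSE]
    if (g$hcount[n_idx] < 1L) next
    if (nrow(heavy) == 0 && g$hcount[n_idx] == 3L) { out <- c(out, n_idx); next } # ammonia
    if (!all(g$elem[heavy[, 1]] == "C")) next
    amide <- any(vapply(heavy[, 1], function(cc) {
      cnb <- g$adj[[cc]]
      any(cnb[, 2] == 2 & g$elem[cnb[, 1]] %in% c("O", "S"))
    }, logical(1)))
    if (amide) next
    out <- c(out, n_idx)
  }
  out
}

#' Classify the reactive amine of a molecule
#'
#' Primary amines whose nitrogen is bonded to an aromatic carbon are
#' `primary_aromatic`; primary amines with only aliphatic carbon neighbors
#' are `primary_aliphatic`; nitrogens bearing two carbon substituents and one
#' hydrogen are `secondary`.
#'
#' @param amine A [molecule] (role `"amine"`) or SMILES string.
#' @return One of `"primary_aliphatic"`, `"primary_aromatic"`, `"secondary"`.
#' @export
classify_amine <- function(amine) {
  smiles <- if (inherits(amine, "molecule")) amine$smiles else amine
  g <- parse_smiles(smiles)
  sites <- find_amine_sites(g)
  if (length(sites) == 0) stop("no reactive amine nitrogen in ", smiles)
  n_idx <- sites[1]
  nb <- g$adj[[n_idx]]
  heavy <- nb[g$elem[nb[, 1]] != "H", 1]
  nh <- g$hcount[n_idx]
  if (length(heavy) >= 3) stop("tertiary amine at the reactive site in ", smiles)
  if (length(heavy) == 2 && nh == 1L) return("secondary")
  if (length(heavy) <= 1 && nh >= 2L) {
    if (length(heavy) == 1 && is_aromatic_carbon(g, heavy[1])) {
      return("primary_aromatic")
    }
    return("primary_aliphatic")
  }
  stop("amine nitrogen in ", smiles, " has unexpected substitution")
}

# Build the condensation product graph: acid minus OH, amine minus one N-H,
# new single C-N bond. Returns list(elem, bonds, charge).
condense_graphs <- function(ga, gm) {
  cg <- find_carboxyl_groups(ga)
  if (length(cg) == 0) stop("acid has no carboxylic acid group: ", ga$smiles)
  if (length(cg) > 1) stop("acid has multiple carboxylic acid groups: ", ga$smiles)
  sites <- find_amine_sites(gm)
  if (length(sites) == 0) stop("no reactive amine nitrogen in ", gm$smiles)
  site <- sites[1]
  drop_a <- c(cg[[1]]$o_hydroxyl, cg[[1]]$h)
  keep_a <- setdiff(seq_len(ga$n), drop_a)
  map_a <- stats::setNames(seq_along(keep_a), keep_a)
  h_on_n <- gm$adj[[site]][gm$elem[gm$adj[[site]][, 1]] == "H", 1][1]
  keep_m <- setdiff(seq_len(gm$n), h_on_n)
  map_m <- stats::setNames(length(keep_a) + seq_along(keep_m), keep_m)
  remap <- function(bonds, keep, map) {
    sel <- bonds[, 1] %in% keep & bonds[, 2] %in% keep
    b <- bonds[sel, , drop = FALSE]
    cbind(i = map[as.character(b[, 1])], j = map[as.character(b[, 2])],
          order = b[, 3])
  }
  bonds <- rbind(remap(ga$bonds, keep_a, map_a), remap(gm$bonds, keep_m, map_m),
                 cbind(i = map_a[[as.character(cg[[1]]$c)]],
                       j = map_m[[as.character(site)]], order = 1L))
  list(elem = c(ga$elem[keep_a], gm$elem[keep_m]),
       bonds = bonds,
       charge = c(ga$charge[keep_a], gm$charge[keep_m]),
       acid_c = map_a[[as.character(cg[[1]]$c)]],
       amine_n = map_m[[as.character(site)]])
}

#' Condense an acid and an amine into the amide product
#'
#' Forms the C-N bond between the carboxyl carbon and the amine nitrogen with
#' loss of water; the result always satisfies the `A + B = C + H2O` formula
#' balance checked by [validate_record()].
#'
#' @param acid,amine [molecule] objects or SMILES strings.
#' @return A product [molecule] with canonical SMILES.
#' @export
condense_product <- function(acid, amine) {
  acid_smi <- if (inherits(acid, "molecule")) acid$smiles else canonicalize(acid)
  amine_smi <- if (inherits(amine, "molecule")) amine$smiles else canonicalize(amine)
  key <- paste0("prod::", acid_smi, ">>", amine_smi)
  smi <- cache_fetch(key, function() {
    gr <- condense_graphs(parse_smiles(acid_smi), parse_smiles(amine_smi))
    molblocks_to_smiles(build_molblock(gr$elem, gr$bonds, gr$charge))
  })
  molecule(smi, "product")
}

# Vectorized product construction over unique (acid, amine) SMILES pairs,
# batching the molblock -> SMILES conversion into one OpenBabel call.
condense_products_batch <- function(acid_smiles, amine_smiles) {
  stopifnot(length(acid_smiles) == length(amine_smiles))
  keys <- paste0("prod::", acid_smiles, ">>", amine_smiles)
  todo <- which(vapply(keys, function(k) is.null(.amideml_cache[[k]]), logical(1)))
  todo <- todo[!duplicated(keys[todo])]
  if (length(todo) > 0) {
    blocks <- vapply(todo, function(i) {
      gr <- condense_graphs(parse_smiles(acid_smiles[i]), parse_smiles(amine_smiles[i]))
      build_molblock(gr$elem, gr$bonds, gr$charge)
    }, character(1))
    smis <- molblocks_to_smiles(blocks)
    for (k in seq_along(todo)) assign(keys[todo[k]], smis[k], envir = .amideml_cache)
  }
  vapply(keys, function(k) .amideml_cache[[k]], character(1), USE.NAMES = FALSE)
}

#' Build the O-acylisourea intermediate from an acid and a carbodiimide
#'
#' Adds the carboxylic acid across one C=N of the carbodiimide: the acyl
#' oxygen bonds to the central carbodiimide carbon and the carboxyl proton
#' moves to a nitrogen, giving R-C(=O)-O-C(=N-R')(NH-R''). For asymmetric
#' carbodiimides (EDC) the proton goes to the nitrogen whose substituent has
#' the smaller heavy-atom count (ties broken by first canonical position),
#' which makes the output deterministic. Mass balance holds exactly:
#' formula(result) = formula(acid) + formula(carbodiimide).
#'
#' @param acid A [molecule] or SMILES string with exactly one carboxyl group.
#' @param coupling_agent `"EDC"`, `"DCC"` or `"DIC"`.
#' @return An intermediate [molecule].
#' @export
make_o_acylisourea <- function(acid, coupling_agent) {
  acid_smi <- if (inherits(acid, "molecule")) acid$smiles else canonicalize(acid)
  coupling_agent <- match.arg(coupling_agent, names(CARBODIIMIDES))
  key <- paste0("oai::", acid_smi, "::", coupling_agent)
  smi <- cache_fetch(key, function() {
    molblocks_to_smiles(o_acylisourea_molblock(acid_smi, coupling_agent))
  })
  molecule(smi, "intermediate")
}

o_acylisourea_molblock <- function(acid_smi, coupling_agent) {
  ga <- parse_smiles(acid_smi)
  gc <- parse_smiles(CARBODIIMIDES[[coupling_agent]])
  cg <- find_carboxyl_groups(ga)
  if (length(cg) == 0) stop("acid has no carboxylic acid group: ", acid_smi)
  if (length(cg) > 1) stop("acid has multiple carboxylic acid groups: ", acid_smi)
  # central carbodiimide carbon: C with two N double bonds
  cdi_c <- which(vapply(seq_len(gc$n), function(i) {
    gc$elem[i] == "C" && !is.null(gc$adj[[i]]) &&
      sum(gc$adj[[i]][, 2] == 2 & gc$elem[gc$adj[[i]][, 1]] == "N") == 2
  }, logical(1)))
  stopifnot(length(cdi_c) == 1)
  ns <- gc$adj[[cdi_c]][gc$adj[[cdi_c]][, 2] == 2, 1]
  # heavy-atom count of each N's substituent branch (excluding the central C)
  branch_size <- vapply(ns, function(n_idx) {
    seen <- c(cdi_c, n_idx); frontier <- n_idx
    while (length(frontier) > 0) {
      nxt <- unique(unlist(lapply(frontier, function(a) g_neighbors(gc, a))))
      nxt <- setdiff(nxt, seen)
      seen <- c(seen, nxt); frontier <- nxt
    }
    sum(gc$elem[setdiff(seen, cdi_c)] != "H")
  }, numeric(1))
  n_h <- ns[order(branch_size, ns)][1]   # proton acceptor
  n_keep <- setdiff(ns, n_h)
  # assemble: acid keeps everything but the O-H hydrogen moves to n_h;
  # acyl O (former hydroxyl) bonds to cdi_c; cdi_c=n_h double bond -> single.
  offset <- ga$n
  bonds_c <- gc$bonds
  sel <- (bonds_c[, 1] == cdi_c & bonds_c[, 2] == n_h) |
         (bonds_c[, 2] == cdi_c & bonds_c[, 1] == n_h)
  bonds_c[sel, "order"] <- 1L
  bonds_c[, 1] <- bonds_c[, 1] + offset
  bonds_c[, 2] <- bonds_c[, 2] + offset
  bonds_a <- ga$bonds
  hsel <- (bonds_a[, 1] == cg[[1]]$o_hydroxyl & bonds_a[, 2] == cg[[1]]$h) |
          (bonds_a[, 2] == cg[[1]]$o_hydroxyl & bonds_a[, 1] == cg[[1]]$h)
  bonds_a <- bonds_a[!hsel, , drop = FALSE]
  new_bonds <- rbind(
    cbind(i = cg[[1]]$o_hydroxyl, j = cdi_c + offset, order = 1L),
    cbind(i = cg[[1]]$h, j = n_h + offset, order = 1L))
  build_molblock(c(ga$elem, gc$elem), rbind(bonds_a, bonds_c, new_bonds),
                 c(ga$charge, gc$charge))
}

g_neighbors <- function(g, i) {
  nb <- g$adj[[i]]
  if (is.null(nb)) integer(0) else nb[, 1]
}

#' Annotate reaction centers of an amide coupling
#'
#' Reaction centers are the atoms whose bond incidence differs between the
#' reactant and product sides: in the acid the carboxyl carbon and the
#' departing hydroxyl oxygen, in the amine the nucleophilic nitrogen, and in
#' the product the amide carbon and nitrogen. The product amide bond is
#' identified by the exact fragment criterion: deleting the candidate C-N
#' bond must split the product into two fragments whose formulas equal
#' formula(acid) - OH and formula(amine) - H. Atom indices refer to heavy +
#' hydrogen positions in the canonical-SMILES atom order of each molecule, so
#' the annotation is invariant to how the input SMILES was numbered.
#'
#' @param acid,amine,product [molecule] objects or SMILES strings.
#' @return A list of class `reaction_centers` with integer index vectors
#'   `acid_atoms`, `amine_atoms`, `product_atoms`.
#' @export
annotate_reaction_centers <- function(acid, amine, product) {
  smi <- function(m) if (inherits(m, "molecule")) m$smiles else canonicalize(m)
  ga <- parse_smiles(smi(acid)); gm <- parse_smiles(smi(amine))
  gp <- parse_smiles(smi(product))
  cg <- find_carboxyl_groups(ga)
  if (length(cg) != 1) stop("acid must have exactly one carboxyl group")
  sites <- find_amine_sites(gm)
  if (length(sites) == 0) stop("no reactive amine nitrogen in ", gm$smiles)
  f_acyl <- formula_subtract(mol_formula(ga$smiles), c(H = 1L, O = 1L))
  f_amine_frag <- formula_subtract(mol_formula(gm$smiles), c(H = 1L))
  # candidate amide C-N bonds in the product
  hit <- NULL
  for (b in seq_len(nrow(gp$bonds))) {
    i <- gp$bonds[b, 1]; j <- gp$bonds[b, 2]
    if (gp$bonds[b, 3] != 1L) next
    pair <- c(gp$elem[i], gp$elem[j])
    if (!setequal(pair, c("C", "N"))) next
    c_idx <- if (gp$elem[i] == "C") i else j
    n_idx <- if (gp$elem[i] == "N") i else j
    cnb <- gp$adj[[c_idx]]
    if (!any(cnb[, 2] == 2 & gp$elem[cnb[, 1]] == "O")) next  # must be acyl C
    frag <- split_formulas_on_bond(gp, c_idx, n_idx)
    if (is.null(frag)) next
    if ((formula_equal(frag$a, f_acyl) && formula_equal(frag$b, f_amine_frag))) {
      hit <- list(c = c_idx, n = n_idx); break
    }
  }
  if (is.null(hit)) {
    stop("no amide bond in the product is consistent with the given acid/amine")
  }
  out <- list(acid_atoms = unname(sort(c(cg[[1]]$c, cg[[1]]$o_hydroxyl))),
              amine_atoms = unname(sites[1]),
              product_atoms = unname(sort(c(hit$c, hit$n))))
  class(out) <- "reaction_centers"
  out
}

# formulas of the two components obtained by deleting bond (i, j); NULL if
# the bond is in a ring (deletion does not disconnect).
split_formulas_on_bond <- function(g, i, j) {
  sel <- !((g$bonds[, 1] == i & g$bonds[, 2] == j) |
           (g$bonds[, 1] == j & g$bonds[, 2] == i))
  el <- g$bonds[sel, c(1, 2), drop = FALSE]
  ig <- igraph::graph_from_edgelist(el, directed = FALSE)
  if (igraph::vcount(ig) < g$n) ig <- igraph::add_vertices(ig, g$n - igraph::vcount(ig))
  comp <- igraph::components(ig)
  if (comp$no != 2) return(NULL)
  side_i <- comp$membership == comp$membership[i]
  tab <- function(sel) {
    t <- table(g$elem[sel]); stats::setNames(as.integer(t), names(t))
  }
  list(a = tab(side_i), b = tab(!side_i))
}

#' Augment a dataset with intermediates and reaction centers
#'
#' Fills each record's O-acylisourea intermediate (from its acid and coupling
#' agent) and attaches reaction-center annotations as an attribute.
#'
#' @param dataset A [reaction_dataset].
#' @param centers Logical; also compute [annotate_reaction_centers()] per
#'   record (stored in `attr(record, "centers")`).
#' @return The augmented [reaction_dataset].
#' @export
augment_dataset <- function(dataset, centers = TRUE) {
  dataset$records <- lapply(dataset$records, function(r) {
    r$intermediate <- make_o_acylisourea(r$acid, r$coupling_agent)
    if (centers) {
      attr(r, "centers") <- annotate_reaction_centers(r$acid, r$amine, r$product)
    }
    r
  })
  dataset
}
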