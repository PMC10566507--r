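# Low-level molecular graph layer.
#
# SMILES parsing, canonicalization and format conversion are delegated to
# OpenBabel (via ChemmineOB); everything downstream works on a light
# molecular-graph structure parsed from V2000 molblocks with explicit
# hydrogens, so that hydrogen counts, formulas and functional-group
# perception need no implicit-valence bookkeeping.

# Session cache for parsed graphs, products, fingerprints, conformers and
# descriptors, keyed by canonical SMILES (+ config hash where relevant).
.amideml_cache <- new.env(parent = emptyenv())

cache_fetch <- function(key, compute) {
  if (!is.null(.amideml_cache[[key]])) return(.amideml_cache[[key]])
  val <- compute()
  assign(key, val, envir = .amideml_cache)
  val
}

#' Clear the internal descriptor cache
#'
#' Drops all memoised molecular graphs, products, fingerprints, conformers
#' and descriptors. Mainly useful in long sessions or benchmarking memory.
#' @return Invisibly, the number of entries dropped.
#' @export
clear_mol_cache <- function() {
  n <- length(ls(.amideml_cache))
  rm(list = ls(.amideml_cache), envir = .amideml_cache)
  invisible(n)
}

# --- SMILES syntax pre-validation -------------------------------------------
# OpenBabel silently truncates some malformed SMILES instead of failing, so
# unbalanced delimiters and dangling ring closures are rejected up front.
smiles_syntax_ok <- function(s) {
  if (!is.character(s) || length(s) != 1 || is.na(s) || !nzchar(s)) return(FALSE)
  if (grepl("[[:space:]]", s)) return(FALSE)
  chars <- strsplit(s, "")[[1]]
  ok_chars <- grepl("^[][A-Za-z0-9@+()=#:/\\\\%.*-]$", chars)
  if (!all(ok_chars)) return(FALSE)
  depth <- 0L; brk <- 0L
  ring <- integer(0)
  i <- 1L
  n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (ch == "(") depth <- depth + 1L
    else if (ch == ")") { depth <- depth - 1L; if (depth < 0L) return(FALSE) }
    else if (ch == "[") { if (brk > 0L) return(FALSE); brk <- 1L }
    else if (ch == "]") { if (brk == 0L) return(FALSE); brk <- 0L }
    else if (brk == 0L && grepl("[0-9]", ch)) {
      d <- as.integer(ch)
      ring <- if (d %in% ring) setdiff(ring, d) else c(ring, d)
    } else if (brk == 0L && ch == "%") {
      if (i + 2L > n || !grepl("^[0-9][0-9]$", paste0(chars[i + 1L], chars[i + 2L])))
        return(FALSE)
      d <- as.integer(paste0(chars[i + 1L], chars[i + 2L]))
      ring <- if (d %in% ring) setdiff(ring, d) else c(ring, d)
      i <- i + 2L
    }
    i <- i + 1L
  }
  depth == 0L && brk == 0L && length(ring) == 0L
}

ob_convert <- function(from, to, source, opts = NULL) {
  if (is.null(opts)) opts <- data.frame(names = character(0), args = character(0))
  suppressWarnings(ChemmineOB::convertFormat(from, to, source, options = opts))
}

#' Canonicalize SMILES strings
#'
#' Converts each SMILES to its canonical form (OpenBabel canonical SMILES).
#' Canonicalization is idempotent: `canonicalize(canonicalize(s))` equals
#' `canonicalize(s)`.
#'
#' @param smiles Character vector of SMILES strings.
#' @return Character vector of canonical SMILES, same length as the input.
#' @examples
#' \dontrun{
#' canonicalize("OC(=O)C") == canonicalize("CC(O)=O")
#' }
#' @export
canonicalize <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) >= 1)
  bad <- !vapply(smiles, smiles_syntax_ok, logical(1))
  if (any(bad)) {
    stop("unparseable SMILES: ", paste(unique(smiles[bad]), collapse = ", "))
  }
  out <- character(length(smiles))
  todo <- !vapply(smiles, function(s) {
    k <- paste0("can::", s)
    !is.null(.amideml_cache[[k]])
  }, logical(1))
  if (any(todo)) {
    res <- ob_convert("SMI", "CAN", paste(smiles[todo], collapse = "\n"))
    lines <- strsplit(res, "\n", fixed = TRUE)[[1]]
    lines <- sub("\t.*$", "", lines)
    lines <- lines[nzchar(lines)]
    if (length(lines) != sum(todo)) {
      stop("SMILES canonicalization failed for one of: ",
           paste(smiles[todo], collapse = ", "))
    }
    for (idx in seq_along(which(todo))) {
      assign(paste0("can::", smiles[todo][idx]), lines[idx], envir = .amideml_cache)
    }
  }
  for (i in seq_along(smiles)) out[i] <- .amideml_cache[[paste0("can::", smiles[i])]]
  out
}

# --- molblock parsing --------------------------------------------------------

parse_molblock <- function(block) {
  lines <- strsplit(block, "\n", fixed = TRUE)[[1]]
  counts <- lines[4]
  na <- as.integer(substr(counts, 1, 3))
  nb <- as.integer(substr(counts, 4, 6))
  if (is.na(na) || is.na(nb)) stop("malformed molblock counts line")
  atom_lines <- lines[5:(4 + na)]
  elem <- trimws(substr(atom_lines, 32, 34))
  coords <- cbind(
    x = as.numeric(substr(atom_lines, 1, 10)),
    y = as.numeric(substr(atom_lines, 11, 20)),
    z = as.numeric(substr(atom_lines, 21, 30))
  )
  bonds <- if (nb > 0) {
    bl <- lines[(5 + na):(4 + na + nb)]
    cbind(
      i = as.integer(substr(bl, 1, 3)),
      j = as.integer(substr(bl, 4, 6)),
      order = as.integer(substr(bl, 7, 9))
    )
  } else {
    cbind(i = integer(0), j = integer(0), order = integer(0))
  }
  charge <- integer(na)
  for (ln in grep("^M  CHG", lines, value = TRUE)) {
    toks <- as.integer(strsplit(trimws(sub("^M  CHG", "", ln)), "\\s+")[[1]])
    nset <- toks[1]
    for (k in seq_len(nset)) {
      charge[toks[2 * k]] <- toks[2 * k + 1]
    }
  }
  list(n = na, elem = elem, coords = coords, bonds = bonds, charge = charge)
}

# Parse a SMILES into an explicit-hydrogen molecular graph (cached).
parse_smiles <- function(smiles) {
  can <- canonicalize(smiles)
  cache_fetch(paste0("graph::", can), function() {
    sdf <- ob_convert("SMI", "SDF", can, data.frame(names = "h", args = ""))
    g <- parse_molblock(sdf)
    g$smiles <- can
    g$heavy <- which(g$elem != "H")
    g$hcount <- integer(g$n)
    for (b in seq_len(nrow(g$bonds))) {
      i <- g$bonds[b, "i"]; j <- g$bonds[b, "j"]
      if (g$elem[i] == "H") g$hcount[j] <- g$hcount[j] + 1L
      if (g$elem[j] == "H") g$hcount[i] <- g$hcount[i] + 1L
    }
    g$adj <- adjacency_list(g)
    g$ring_atom <- ring_membership(g)
    g
  })
}

adjacency_list <- function(g) {
  adj <- vector("list", g$n)
  for (b in seq_len(nrow(g$bonds))) {
    i <- g$bonds[b, "i"]; j <- g$bonds[b, "j"]; o <- g$bonds[b, "order"]
    adj[[i]] <- rbind(adj[[i]], c(j, o))
    adj[[j]] <- rbind(adj[[j]], c(i, o))
  }
  adj
}

# atoms that lie on at least one cycle (via igraph biconnected components)
ring_membership <- function(g) {
  inring <- logical(g$n)
  if (nrow(g$bonds) == 0) return(inring)
  ig <- igraph::graph_from_edgelist(g$bonds[, c("i", "j"), drop = FALSE],
                                    directed = FALSE)
  if (igraph::vcount(ig) < g$n) ig <- igraph::add_vertices(ig, g$n - igraph::vcount(ig))
  bc <- igraph::biconnected_components(ig)
  for (comp in bc$components) {
    v <- as.integer(comp)
    if (length(v) >= 3) inring[v] <- TRUE
  }
  inring
}

# A carbon counts as aromatic if it sits in a ring and carries a double bond
# to another ring atom (kekulized molblocks); adequate for the benzenoid and
# heteroaromatic rings this package's chemical space contains.
is_aromatic_carbon <- function(g, idx) {
  if (g$elem[idx] != "C" || !g$ring_atom[idx]) return(FALSE)
  nb <- g$adj[[idx]]
  if (is.null(nb)) return(FALSE)
  any(nb[, 2] == 2 & g$ring_atom[nb[, 1]] & g$elem[nb[, 1]] %in% c("C", "N", "O", "S"))
}

# --- formulas ----------------------------------------------------------------

#' Molecular formula of a SMILES
#'
#' Counts atoms (including hydrogens) per element.
#' @param smiles A single SMILES string.
#' @return Named integer vector of element counts, alphabetical by symbol.
#' @export
mol_formula <- function(smiles) {
  g <- parse_smiles(smiles)
  tab <- table(g$elem)
  out <- as.integer(tab)
  names(out) <- names(tab)
  out[order(names(out))]
}

formula_add <- function(a, b) {
  els <- sort(union(names(a), names(b)))
  out <- stats::setNames(integer(length(els)), els)
  out[names(a)] <- out[names(a)] + a
  out[names(b)] <- out[names(b)] + b
  out
}

formula_subtract <- function(a, b) {
  els <- sort(union(names(a), names(b)))
  out <- stats::setNames(integer(length(els)), els)
  out[names(a)] <- out[names(a)] + a
  out[names(b)] <- out[names(b)] - b
  out[out != 0L]
}

formula_equal <- function(a, b) {
  a <- a[a != 0L]; b <- b[b != 0L]
  length(a) == length(b) && all(sort(names(a)) == sort(names(b))) &&
    all(a[sort(names(a))] == b[sort(names(b))])
}

formula_string <- function(f) {
  f <- f[f != 0L]
  ord <- c(intersect(c("C", "H"), names(f)), sort(setdiff(names(f), c("C", "H"))))
  paste0(vapply(ord, function(e) {
    if (f[[e]] == 1L) e else paste0(e, f[[e]])
  }, character(1)), collapse = "")
}

# --- building molblocks back from edited graphs ------------------------------

build_molblock <- function(elem, bonds, charge = NULL, coords = NULL) {
  n <- length(elem)
  if (is.null(coords)) coords <- matrix(0, n, 3)
  if (is.null(charge)) charge <- integer(n)
  hdr <- c("", " amideml", "",
           sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nrow(bonds)))
  at <- sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                coords[, 1], coords[, 2], coords[, 3], elem)
  bd <- if (nrow(bonds) > 0) {
    sprintf("%3d%3d%3d  0  0  0  0", bonds[, 1], bonds[, 2], bonds[, 3])
  } else character(0)
  chg <- character(0)
  nz <- which(charge != 0L)
  if (length(nz) > 0) {
    chg <- paste0("M  CHG", sprintf("%3d", length(nz)),
                  paste0(sprintf("%4d%4d", nz, charge[nz]), collapse = ""))
  }
  paste(c(hdr, at, bd, chg, "M  END", "$$$$"), collapse = "\n")
}

# Canonical SMILES for one or many molblocks in a single OpenBabel call.
molblocks_to_smiles <- function(blocks) {
  res <- ob_convert("SDF", "CAN", paste(blocks, collapse = "\n"))
  lines <- strsplit(res, "\n", fixed = TRUE)[[1]]
  lines <- sub("[\t ].*$", "", lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) != length(blocks)) {
    stop("molblock to SMILES conversion lost ", length(blocks) - length(lines),
         " molecule(s)")
  }
  lines
}
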