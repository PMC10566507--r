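# Morgan (ECFP-style) circular fingerprints on the heavy-atom graph.
#
# Atom environments of increasing radius are hashed with a deterministic
# integer polynomial hash and folded onto a fixed-width bit vector, so the
# fingerprint is bit-exact across platforms and sessions.

HASH_MOD <- 2147483647  # 2^31 - 1; keeps double arithmetic exact (< 2^53)
HASH_MUL <- 1000003

hash_ints <- function(v) {
  h <- 5381
  for (x in v) h <- (h * HASH_MUL + x + 1) %% HASH_MOD
  h
}

ATOMIC_NUMBER <- c(H = 1, B = 5, C = 6, N = 7, O = 8, F = 9, Si = 14, P = 15,
                   S = 16, Cl = 17, Br = 35, I = 53)

# heavy-atom view of an explicit-H graph: elements, H counts, adjacency with
# bond orders, ring membership
heavy_view <- function(g) {
  heavy <- g$heavy
  idx <- stats::setNames(seq_along(heavy), heavy)
  adj <- vector("list", length(heavy))
  for (b in seq_len(nrow(g$bonds))) {
    i <- g$bonds[b, 1]; j <- g$bonds[b, 2]; o <- g$bonds[b, 3]
    if (g$elem[i] == "H" || g$elem[j] == "H") next
    hi <- idx[[as.character(i)]]; hj <- idx[[as.character(j)]]
    adj[[hi]] <- rbind(adj[[hi]], c(hj, o))
    adj[[hj]] <- rbind(adj[[hj]], c(hi, o))
  }
  list(n = length(heavy), elem = g$elem[heavy], hcount = g$hcount[heavy],
       charge = g$charge[heavy], ring = g$ring_atom[heavy], adj = adj)
}

#' Morgan fingerprint of a molecule
#'
#' Circular fingerprint hashing atom environments of radius 0..`radius` into
#' a binary vector of length `n_bits`. Identical canonical SMILES give
#' bit-identical vectors.
#'
#' @param mol A [molecule] or SMILES string.
#' @param radius Maximum environment radius (bond count), default 2.
#' @param n_bits Folded fingerprint width, default 2048.
#' @return Integer vector of 0/1 of length `n_bits`.
#' @export
morgan_fingerprint <- function(mol, radius = 2L, n_bits = 2048L) {
  if (n_bits <= 0) stop("n_bits must be positive")
  smiles <- if (inherits(mol, "molecule")) mol$smiles else canonicalize(mol)
  key <- paste0("fp::", smiles, "::", radius, "::", n_bits)
  cache_fetch(key, function() {
    h <- heavy_view(parse_smiles(smiles))
    fp <- integer(n_bits)
    if (h$n == 0) return(fp)
    ids <- vapply(seq_len(h$n), function(i) {
      hash_ints(c(ATOMIC_NUMBER[[h$elem[i]]], length(g_rows(h$adj[[i]])),
                  h$hcount[i], h$charge[i], as.integer(h$ring[i])))
    }, numeric(1))
    all_ids <- ids
    for (r in seq_len(radius)) {
      new_ids <- vapply(seq_len(h$n), function(i) {
        nb <- h$adj[[i]]
        if (is.null(nb)) return(hash_ints(c(r, ids[i])))
        pairs <- cbind(nb[, 2], ids[nb[, 1]])
        ord <- order(pairs[, 1], pairs[, 2])
        hash_ints(c(r, ids[i], t(pairs[ord, , drop = FALSE])))
      }, numeric(1))
      ids <- new_ids
      all_ids <- c(all_ids, ids)
    }
    fp[unique(all_ids %% n_bits) + 1] <- 1L
    fp
  })
}

g_rows <- function(m) if (is.null(m)) integer(0) else seq_len(nrow(m))

#' Tanimoto similarity of two binary fingerprints
#' @param a,b Binary integer vectors of equal length.
#' @return Tanimoto coefficient in `[0, 1]`.
#' @export
tanimoto <- function(a, b) {
  stopifnot(length(a) == length(b))
  inter <- sum(a & b)
  uni <- sum(a | b)
  if (uni == 0) return(0)
  inter / uni
}
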