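# Circular (ECFP-style) fingerprints over heavy atoms, used for similarity
# and confidence scoring only (the network never sees them).

# 32-bit FNV-1a over the bytes of a string, with exact mod-2^32 arithmetic
# (the multiply is split into 16-bit halves so doubles never lose precision).
.fnv1a <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor_dbl(h, b)
    hi <- h %/% 65536
    lo <- h %% 65536
    h <- ((hi * 16777619) %% 65536) * 65536 + lo * 16777619
    h <- h %% 4294967296
  }
  h
}

# bitwXor on doubles in [0, 2^32)
bitwXor_dbl <- function(a, b) {
  hi <- bitwXor(a %/% 65536, b %/% 65536)
  lo <- bitwXor(a %% 65536, b %% 65536)
  hi * 65536 + lo
}

#' Circular fingerprint of a molecule
#'
#' Hashes iteratively grown heavy-atom neighborhoods: at radius 0 each heavy
#' atom gets an identifier from its invariants (element, formal charge,
#' aromatic flag); each further round rehashes the atom's identifier together
#' with the sorted (bond category, neighbor identifier) list of its bonded
#' heavy neighbors, so an identifier at radius r encodes the substructure
#' within r bonds. All identifiers from all rounds are folded onto `n_bits`
#' bits. Deliberately degree-free at radius 0, so e.g. the carbons of methane
#' and ethane share their radius-0 bit.
#'
#' @param mol a [molecule()].
#' @param radius neighborhood radius in bonds (>= 0).
#' @param n_bits fold width.
#' @return object of class `fingerprint`: sorted integer vector of set bits
#'   (0-based), with attributes `n_bits` and `radius`.
#' @export
circular_fingerprint <- function(mol, radius = 2L, n_bits = 2048L) {
  stopifnot(radius >= 0L, n_bits >= 2L)
  heavy <- which(mol$elements != "H")
  if (!length(heavy)) heavy <- seq_along(mol$elements)  # H2 etc.
  arom <- compute_ring_membership(mol)$aromatic
  kek <- kekulize_orders(mol)
  ids <- vapply(heavy, function(a)
    .fnv1a(paste(mol$elements[a], mol$charges[a],
                 as.integer(arom[a]), sep = ":")), numeric(1))
  names(ids) <- heavy
  nbrs <- bond_neighbor_list(mol)
  all_ids <- ids
  if (radius > 0L) {
    for (r in seq_len(radius)) {
      new_ids <- ids
      for (pos in seq_along(heavy)) {
        a <- heavy[pos]
        hb <- intersect(nbrs[[a]], heavy)
        if (!length(hb)) next
        parts <- vapply(hb, function(b) {
          k <- which((mol$bonds$i == a & mol$bonds$j == b) |
                     (mol$bonds$i == b & mol$bonds$j == a))[1L]
          sprintf("%d-%.0f", kek[k], ids[[as.character(b)]])
        }, character(1))
        new_ids[[pos]] <- .fnv1a(paste(ids[[pos]], paste(sort(parts),
                                                         collapse = "|")))
      }
      ids <- new_ids
      all_ids <- c(all_ids, ids)
    }
  }
  bits <- sort(unique(as.integer(all_ids %% n_bits)))
  structure(bits, class = "fingerprint", n_bits = as.integer(n_bits),
            radius = as.integer(radius))
}

#' Tanimoto similarity between two fingerprints
#'
#' `|A intersect B| / |A union B|` over the set bits.
#'
#' @param fpA,fpB [circular_fingerprint()] results (or bare integer sets).
#' @return similarity in `[0, 1]`.
#' @export
tanimoto <- function(fpA, fpB) {
  a <- unique(as.integer(fpA)); b <- unique(as.integer(fpB))
  if (!length(a) && !length(b)) stop("both fingerprints are empty")
  length(intersect(a, b)) / length(union(a, b))
}

#' Summarize fingerprint similarity within and between compound sets
#'
#' Two aggregation conventions are in circulation for statements like "the
#' average similarity within training sets" and both are reported here: the
#' mean over all unordered pairs (`mean_pairwise`), and the mean over
#' compounds of each compound's maximum similarity to the other set
#' (`mean_of_max`; within one set, to any *other* member). For a
#' train-versus-test comparison pass both arguments; with only `set_a` the
#' within-set summary is returned.
#'
#' @param set_a,set_b lists of [molecule()]s or `fingerprint`s; `set_b`
#'   optional.
#' @param radius,n_bits fingerprint settings.
#' @return list with `mean_pairwise` and `mean_of_max`.
#' @export
similarity_summary <- function(set_a, set_b = NULL, radius = 2L,
                               n_bits = 2048L) {
  as_fp <- function(x) if (inherits(x, "fingerprint")) x
                       else circular_fingerprint(x, radius, n_bits)
  fa <- lapply(set_a, as_fp)
  if (is.null(set_b)) {
    stopifnot(length(fa) >= 2L)
    S <- outer(seq_along(fa), seq_along(fa),
               Vectorize(function(i, j) tanimoto(fa[[i]], fa[[j]])))
    off <- S[upper.tri(S)]
    diag(S) <- -Inf
    list(mean_pairwise = mean(off), mean_of_max = mean(apply(S, 1L, max)))
  } else {
    fb <- lapply(set_b, as_fp)
    S <- outer(seq_along(fa), seq_along(fb),
               Vectorize(function(i, j) tanimoto(fa[[i]], fb[[j]])))
    list(mean_pairwise = mean(S), mean_of_max = mean(apply(S, 1L, max)))
  }
}

#' Prediction confidence from training-set similarity
#'
#' Scores how well a query molecule is covered by the training set: the
#' confidence is its maximum Tanimoto similarity to any training molecule,
#' and the most similar training molecules are returned so a chemist can
#' inspect what the model is leaning on.
#'
#' @param query a [molecule()] or `fingerprint`.
#' @param training list of [molecule()]s or `fingerprint`s (nonempty).
#' @param top_n how many nearest training molecules to report.
#' @param radius,n_bits fingerprint settings (used when molecules are given).
#' @return list with `score` (max similarity) and `neighbors` (data.frame
#'   with columns `index`, `id`, `similarity`, sorted descending).
#' @export
confidence_score <- function(query, training, top_n = 5L, radius = 2L,
                             n_bits = 2048L) {
  stopifnot(length(training) >= 1L)
  as_fp <- function(x) if (inherits(x, "fingerprint")) x
                       else circular_fingerprint(x, radius, n_bits)
  qfp <- as_fp(query)
  fps <- lapply(training, as_fp)
  sims <- vapply(fps, tanimoto, numeric(1), fpB = qfp)
  ids <- vapply(seq_along(training), function(i) {
    m <- training[[i]]
    if (inherits(m, "molecule")) m$id else as.character(i)
  }, character(1))
  ord <- order(-sims, seq_along(sims))[seq_len(min(top_n, length(sims)))]
  list(score = max(sims),
       neighbors = data.frame(index = ord, id = ids[ord],
                              similarity = sims[ord]))
}
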