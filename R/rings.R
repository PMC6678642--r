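# Ring perception on the bond graph.
#
# Rings are taken as a smallest-set-of-smallest-rings (SSSR): for every bond
# the shortest cycle through it is found by BFS on the graph with that bond
# removed; candidates are scanned in order of size and kept while their
# edge-incidence vectors are independent over GF(2), until the cycle-space
# dimension (m - n + components) is reached.

# shortest path u..v avoiding edge (u,v); returns atom index path or NULL
.bfs_path <- function(nbrs, u, v) {
  n <- length(nbrs)
  prev <- integer(n); seen <- logical(n)
  queue <- u; seen[u] <- TRUE
  while (length(queue)) {
    a <- queue[1L]; queue <- queue[-1L]
    for (b in nbrs[[a]]) {
      if (a == u && b == v) next  # the removed edge
      if (!seen[b]) {
        seen[b] <- TRUE; prev[b] <- a
        if (b == v) {
          path <- v
          while (path[1L] != u) path <- c(prev[path[1L]], path)
          return(path)
        }
        queue <- c(queue, b)
      }
    }
  }
  NULL
}

.n_components <- function(nbrs) {
  n <- length(nbrs); seen <- logical(n); k <- 0L
  for (s in seq_len(n)) {
    if (seen[s]) next
    k <- k + 1L
    queue <- s; seen[s] <- TRUE
    while (length(queue)) {
      a <- queue[1L]; queue <- queue[-1L]
      fresh <- nbrs[[a]][!seen[nbrs[[a]]]]
      seen[fresh] <- TRUE
      queue <- c(queue, fresh)
    }
  }
  k
}

#' Perceive the ring system of a molecule
#'
#' Returns the smallest set of smallest rings of the bond graph as a list of
#' atom-index cycles, together with a per-ring aromatic call. A ring is called
#' aromatic when every bond along it is annotated aromatic (order 4), or, in
#' Kekule-drawn input, when it is six-membered and single/double bond orders
#' alternate around it; explicit per-atom annotations on the molecule take
#' precedence downstream.
#'
#' @param mol a [molecule()].
#' @return list with `rings` (list of integer vectors, each a cycle of atom
#'   indices) and `aromatic` (logical per ring).
#' @export
perceive_rings <- function(mol) {
  n <- n_atoms(mol)
  bonds <- mol$bonds
  m <- nrow(bonds)
  nbrs <- bond_neighbor_list(mol)
  dim_cycle <- m - n + .n_components(nbrs)
  if (dim_cycle <= 0L)
    return(list(rings = list(), aromatic = logical()))

  edge_id <- function(i, j) paste(pmin(i, j), pmax(i, j))
  eids <- edge_id(bonds$i, bonds$j)
  order_of <- structure(bonds$order, names = eids)

  cands <- list()
  for (k in seq_len(m)) {
    path <- .bfs_path(nbrs, bonds$i[k], bonds$j[k])
    if (!is.null(path)) cands[[length(cands) + 1L]] <- path
  }
  if (!length(cands)) return(list(rings = list(), aromatic = logical()))
  cands <- cands[order(lengths(cands))]

  ring_edge_vec <- function(ring) {
    v <- logical(m)
    nxt <- c(ring[-1L], ring[1L])
    v[match(edge_id(ring, nxt), eids)] <- TRUE
    v
  }

  basis <- list()   # GF(2) row-echelon basis, each with a pivot index
  pivots <- integer()
  chosen <- list()
  for (ring in cands) {
    vec <- ring_edge_vec(ring)
    for (b in seq_along(basis))
      if (vec[pivots[b]]) vec <- xor(vec, basis[[b]])
    if (any(vec)) {
      basis[[length(basis) + 1L]] <- vec
      pivots <- c(pivots, which(vec)[1L])
      chosen[[length(chosen) + 1L]] <- ring
      if (length(chosen) == dim_cycle) break
    }
  }

  arom <- vapply(chosen, function(ring) {
    nxt <- c(ring[-1L], ring[1L])
    orders <- unname(order_of[edge_id(ring, nxt)])
    if (all(orders == 4L)) return(TRUE)
    length(ring) == 6L && all(sort(unique(orders)) == c(1L, 2L)) &&
      all(abs(diff(c(orders, orders[1L]))) == 1L)
  }, logical(1))

  list(rings = chosen, aromatic = arom)
}

#' Per-atom ring membership counts and aromatic flags
#'
#' For every atom, counts the perceived rings of each size 3 through 8 that
#' contain it (larger rings are ignored), and flags atoms on aromatic rings.
#' Explicit aromatic annotations carried by the molecule override perception.
#'
#' @param mol a [molecule()].
#' @return list with `ring_counts` (n x 6 integer matrix, columns are ring
#'   sizes 3:8) and `aromatic` (logical per atom).
#' @export
compute_ring_membership <- function(mol) {
  n <- n_atoms(mol)
  counts <- matrix(0L, n, 6L, dimnames = list(NULL, paste0("ring", 3:8)))
  per <- perceive_rings(mol)
  arom <- logical(n)
  for (k in seq_along(per$rings)) {
    ring <- per$rings[[k]]
    sz <- length(ring)
    if (sz >= 3L && sz <= 8L)
      counts[ring, sz - 2L] <- counts[ring, sz - 2L] + 1L
    if (per$aromatic[k]) arom[ring] <- TRUE
  }
  if (!is.null(mol$aromatic)) arom <- as.logical(mol$aromatic)
  list(ring_counts = counts, aromatic = arom)
}

# TRUE for atom pairs that sit on a common perceived ring
same_ring_matrix <- function(mol, rings = perceive_rings(mol)$rings) {
  n <- n_atoms(mol)
  sr <- matrix(FALSE, n, n)
  for (ring in rings) sr[ring, ring] <- TRUE
  diag(sr) <- FALSE
  sr
}

# Map bond orders onto the {Single, Double} scheme of the pair features:
# triple -> Double; aromatic (order 4) -> alternating Kekule assignment via a
# greedy matching on the aromatic subgraph (matched bonds Double, rest Single).
kekulize_orders <- function(mol) {
  bonds <- mol$bonds
  out <- integer(nrow(bonds))
  if (!nrow(bonds)) return(out)
  out[bonds$order == 1L] <- 1L
  out[bonds$order == 2L] <- 2L
  out[bonds$order == 3L] <- 2L
  ar <- which(bonds$order == 4L)
  if (length(ar)) {
    used <- logical(n_atoms(mol))
    for (k in ar[order(bonds$i[ar], bonds$j[ar])]) {
      i <- bonds$i[k]; j <- bonds$j[k]
      if (!used[i] && !used[j]) {
        out[k] <- 2L; used[i] <- TRUE; used[j] <- TRUE
      } else out[k] <- 1L
    }
  }
  out[out == 0L] <- 1L
  out
}
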