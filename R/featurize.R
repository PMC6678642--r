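#' Featurizer configuration
#'
#' Settings that control how a molecule is turned into a feature graph.
#' Neighborhoods combine the bond graph with a spatial cutoff: an atom's
#' neighbors are all atoms it is bonded to plus all atoms within
#' `distance_cutoff`, truncated to the `max_neighbors` nearest with bonded
#' atoms never dropped, then symmetrized.
#'
#' @param distance_cutoff spatial neighbor cutoff in Angstrom.
#' @param max_neighbors cap on neighbors per atom (bonded atoms exempt).
#' @param vocab element vocabulary for the 23-slot atom-type one-hot
#'   (22 named elements; everything else maps to the trailing "other" slot).
#' @return A list of class `graph_config`.
#' @export
graph_config <- function(distance_cutoff = 4.0, max_neighbors = 12L,
                         vocab = default_element_vocab()) {
  stopifnot(distance_cutoff > 0, max_neighbors >= 1L, length(vocab) == 22L)
  structure(list(distance_cutoff = distance_cutoff,
                 max_neighbors = as.integer(max_neighbors), vocab = vocab),
            class = "graph_config")
}

#' Number of atom feature channels
#' @return 33: atom-type one-hot (23) + radii (2) + ring counts 3-8 (6) +
#'   aromatic flag (1) + formal charge (1).
#' @export
atom_feature_width <- function() 33L

#' Number of atom-pair feature channels
#' @return 5: bond-type one-hot Single/Double/None (3) + distance (1) +
#'   same-ring flag (1).
#' @export
pair_feature_width <- function() 5L

#' Featurize the atoms of a molecule
#'
#' Builds the n x 33 atom feature block: a 23-wide element one-hot (unknown
#' elements set the "other" slot), van der Waals and covalent radii, counts of
#' perceived rings of sizes 3-8 containing the atom, an aromatic flag and the
#' formal charge.
#'
#' @param mol a [molecule()].
#' @param vocab 22-element vocabulary (see [graph_config()]).
#' @param rings optional precomputed [compute_ring_membership()] result.
#' @return numeric matrix, one row per atom, 33 columns.
#' @export
featurize_atoms <- function(mol, vocab = default_element_vocab(),
                            rings = compute_ring_membership(mol)) {
  n <- n_atoms(mol)
  stopifnot(length(vocab) == 22L)
  onehot <- matrix(0, n, 23L)
  slot <- match(mol$elements, vocab)
  slot[is.na(slot)] <- 23L
  onehot[cbind(seq_len(n), slot)] <- 1
  rad <- element_radii(mol$elements)
  out <- cbind(onehot, rad$vdw, rad$covalent, rings$ring_counts,
               as.numeric(rings$aromatic), as.numeric(mol$charges))
  colnames(out) <- c(paste0("type_", c(vocab, "other")), "vdw", "covalent",
                     paste0("ring", 3:8), "aromatic", "charge")
  out
}

#' Determine the neighborhood of every atom
#'
#' Neighbors of atom `a` are the atoms bonded to `a` together with all atoms
#' within the spatial cutoff, truncated to the `max_neighbors` nearest by
#' distance (bonded atoms are never truncated), and finally symmetrized so
#' that `b in N(a)` implies `a in N(b)`.
#'
#' @param mol a [molecule()].
#' @param distance_cutoff cutoff in Angstrom.
#' @param max_neighbors per-atom cap.
#' @return list of sorted integer neighbor vectors, one per atom.
#' @export
determine_neighbors <- function(mol, distance_cutoff = 4.0,
                                max_neighbors = 12L) {
  stopifnot(distance_cutoff > 0)
  n <- n_atoms(mol)
  if (n == 1L) return(list(integer()))
  d <- as.matrix(stats::dist(mol$coords))
  bonded <- bond_neighbor_list(mol)
  nb <- vector("list", n)
  for (a in seq_len(n)) {
    spatial <- setdiff(which(d[a, ] <= distance_cutoff), a)
    cand <- union(bonded[[a]], spatial)
    if (length(cand) > max_neighbors) {
      extra <- setdiff(cand, bonded[[a]])
      room <- max_neighbors - length(bonded[[a]])
      keep <- if (room > 0L) extra[order(d[a, extra])][seq_len(min(room, length(extra)))]
              else integer()
      cand <- c(bonded[[a]], keep)
    }
    nb[[a]] <- cand
  }
  for (a in seq_len(n))           # symmetrize (union keeps bonded intact)
    for (b in nb[[a]]) if (!(a %in% nb[[b]])) nb[[b]] <- c(nb[[b]], a)
  lapply(nb, function(v) sort(unique(as.integer(v))))
}

#' Featurize one atom pair
#'
#' Emits the 5-vector for a neighbor pair: bond-type one-hot over
#' {Single, Double, None} (aromatic bonds are Kekule-assigned, triple bonds
#' count as Double, spatial-only neighbors as None), the Euclidean distance in
#' Angstrom, and a flag set when both atoms share a perceived ring. The
#' features are symmetric in the pair by construction.
#'
#' @param a,b atom indices (must differ).
#' @param mol a [molecule()].
#' @param context optional precomputed list with `kek` (kekulized bond orders)
#'   and `same_ring` (matrix); built on the fly when absent.
#' @return numeric length-5 vector.
#' @export
featurize_pair <- function(a, b, mol, context = NULL) {
  if (a == b) stop("a pair needs two distinct atoms")
  if (is.null(context))
    context <- list(kek = kekulize_orders(mol), same_ring = same_ring_matrix(mol))
  hit <- which((mol$bonds$i == a & mol$bonds$j == b) |
               (mol$bonds$i == b & mol$bonds$j == a))
  slot <- if (length(hit)) context$kek[hit[1L]] else 3L  # None
  onehot <- numeric(3); onehot[slot] <- 1
  dist <- sqrt(sum((mol$coords[a, ] - mol$coords[b, ])^2))
  out <- c(onehot, dist, as.numeric(context$same_ring[a, b]))
  names(out) <- c("single", "double", "none", "distance", "same_ring")
  out
}

#' Build the feature graph of a molecule
#'
#' Combines [featurize_atoms()], [determine_neighbors()] and
#' [featurize_pair()] into the graph structure consumed by the network:
#' per-atom feature rows, neighbor lists, and a pair-feature row for every
#' directed neighbor edge.
#'
#' @param mol a [molecule()].
#' @param config a [graph_config()].
#' @return An object of class `mol_graph`: list with `atom_features` (n x 33),
#'   `neighbors` (list), `edges` (list with integer vectors `center`, `nbr`
#'   and matrix `pair`, one row per directed edge), `n_atoms`, `id`.
#' @export
build_graph <- function(mol, config = graph_config()) {
  stopifnot(inherits(mol, "molecule"))
  rings <- perceive_rings(mol)
  membership <- compute_ring_membership(mol)
  af <- featurize_atoms(mol, config$vocab, membership)
  nb <- determine_neighbors(mol, config$distance_cutoff, config$max_neighbors)
  ctx <- list(kek = kekulize_orders(mol),
              same_ring = same_ring_matrix(mol, rings$rings))
  center <- rep.int(seq_along(nb), lengths(nb))
  nbr <- as.integer(unlist(nb, use.names = FALSE))
  if (length(center)) {
    pair <- t(mapply(featurize_pair, center, nbr,
                     MoreArgs = list(mol = mol, context = ctx)))
  } else {
    pair <- matrix(0, 0L, pair_feature_width())
  }
  structure(list(atom_features = af, neighbors = nb,
                 edges = list(center = center, nbr = nbr, pair = pair),
                 n_atoms = n_atoms(mol), id = mol$id),
            class = "mol_graph")
}

#' @export
print.mol_graph <- function(x, ...) {
  cat(sprintf("<mol_graph %s: %d atoms, %d directed neighbor edges>\n",
              x$id, x$n_atoms, length(x$edges$center)))
  invisible(x)
}

#' Dump a feature graph as JSON (debugging aid)
#'
#' @param graph a [build_graph()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_graph_json <- function(graph, path) {
  obj <- list(id = graph$id, n_atoms = graph$n_atoms,
              atom_features = graph$atom_features,
              neighbors = graph$neighbors,
              edge_center = graph$edges$center, edge_nbr = graph$edges$nbr,
              pair_features = graph$edges$pair)
  jsonlite::write_json(obj, path, digits = 10, auto_unbox = TRUE)
  invisible(path)
}
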