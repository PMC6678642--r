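#' Construct a molecule
#'
#' A light container for a small molecule with explicit 3D coordinates:
#' the unit every featurization and prediction routine consumes. Hydrogens
#' may be present or not; the featurizer treats whatever atoms are given.
#'
#' @param id compound identifier (string).
#' @param elements character vector of element symbols, one per atom.
#' @param coords numeric matrix (n x 3) of Cartesian coordinates in Angstrom.
#' @param bonds data.frame with integer columns `i`, `j` and a column `order`
#'   (1 = single, 2 = double, 3 = triple, 4 = aromatic), one row per bond.
#'   May have zero rows.
#' @param charges integer formal charges per atom (default all 0).
#' @param aromatic optional logical per-atom aromatic annotation; if `NULL`
#'   aromaticity is perceived from the bond graph when needed.
#' @param smiles optional SMILES string (metadata only).
#' @param date optional registration date (`Date` or parseable string).
#'
#' @return An object of class `molecule`.
#' @export
molecule <- function(id, elements, coords, bonds = empty_bonds(),
                     charges = integer(length(elements)), aromatic = NULL,
                     smiles = NULL, date = NULL) {
  n <- length(elements)
  if (n < 1L) stop("a molecule needs at least one atom")
  coords <- as.matrix(coords)
  if (!is.numeric(coords) || ncol(coords) != 3L || nrow(coords) != n)
    stop("coords must be an n x 3 numeric matrix")
  if (any(!is.finite(coords))) stop("coordinates must be finite")
  bonds <- as.data.frame(bonds)
  if (nrow(bonds)) {
    if (!all(c("i", "j", "order") %in% names(bonds)))
      stop("bonds needs columns i, j, order")
    bonds$i <- as.integer(bonds$i); bonds$j <- as.integer(bonds$j)
    if (any(bonds$i == bonds$j)) stop("self-bonds are not allowed")
    if (any(bonds$i < 1L | bonds$i > n | bonds$j < 1L | bonds$j > n))
      stop("bond endpoints out of range")
  }
  if (length(charges) != n) stop("one formal charge per atom required")
  if (!is.null(aromatic) && length(aromatic) != n)
    stop("one aromatic flag per atom required")
  if (!is.null(date)) date <- as.Date(date)
  structure(list(id = as.character(id), elements = as.character(elements),
                 coords = coords, bonds = bonds,
                 charges = as.integer(charges), aromatic = aromatic,
                 smiles = smiles, date = date),
            class = "molecule")
}

#' @export
#' @rdname molecule
empty_bonds <- function() {
  data.frame(i = integer(), j = integer(), order = integer())
}

#' @export
print.molecule <- function(x, ...) {
  cat(sprintf("<molecule %s: %d atoms (%s), %d bonds>\n", x$id,
              length(x$elements),
              paste(names(sort(-table(x$elements))), collapse = ","),
              nrow(x$bonds)))
  invisible(x)
}

n_atoms <- function(mol) length(mol$elements)

#' Relabel the atoms of a molecule
#'
#' Applies a permutation to the atom order, remapping bonds, charges,
#' coordinates and aromatic flags consistently. Used to assert permutation
#' invariance of featurization and predictions.
#'
#' @param mol a [molecule()].
#' @param perm integer permutation of `1:n_atoms`; `perm[k]` is the old index
#'   placed at new position `k`.
#' @return The permuted `molecule`.
#' @export
permute_molecule <- function(mol, perm) {
  n <- n_atoms(mol)
  stopifnot(length(perm) == n, all(sort(perm) == seq_len(n)))
  inv <- integer(n); inv[perm] <- seq_len(n)
  bonds <- mol$bonds
  if (nrow(bonds)) { bonds$i <- inv[bonds$i]; bonds$j <- inv[bonds$j] }
  molecule(mol$id, mol$elements[perm], mol$coords[perm, , drop = FALSE],
           bonds, mol$charges[perm],
           if (is.null(mol$aromatic)) NULL else mol$aromatic[perm],
           mol$smiles, mol$date)
}

# n x n logical adjacency from the bond list
bond_adjacency <- function(mol) {
  n <- n_atoms(mol)
  adj <- matrix(FALSE, n, n)
  if (nrow(mol$bonds)) {
    adj[cbind(mol$bonds$i, mol$bonds$j)] <- TRUE
    adj[cbind(mol$bonds$j, mol$bonds$i)] <- TRUE
  }
  adj
}

# adjacency as neighbor index lists
bond_neighbor_list <- function(mol) {
  n <- n_atoms(mol)
  out <- rep(list(integer()), n)
  if (nrow(mol$bonds)) {
    e <- rbind(cbind(mol$bonds$i, mol$bonds$j), cbind(mol$bonds$j, mol$bonds$i))
    sp <- split(e[, 2L], e[, 1L])
    out[as.integer(names(sp))] <- lapply(sp, function(v) sort(unique(v)))
  }
  out
}
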