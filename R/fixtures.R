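#' Specification for the synthetic molecule generator
#'
#' Describes the study conditions for generated fixtures: small drug-like
#' heavy-atom skeletons over a fixed element alphabet, valence-respecting
#' random trees with occasional 3-6 membered ring closures, deterministic
#' spring-layout 3D geometry at ~1.5 Angstrom bond lengths, and synthetic
#' registration dates in generation order.
#'
#' @param n number of molecules.
#' @param seed generator seed; a fixed seed reproduces the output exactly.
#' @param alphabet element alphabet (must have known valences).
#' @param size_range inclusive atom-count range.
#' @param ring_prob probability that a molecule receives a ring closure.
#' @param double_bond_prob probability a tree bond with spare valence on
#'   both ends is upgraded to a double bond.
#' @param sigma default label noise standard deviation.
#' @return list of class `fixture_spec`.
#' @export
fixture_spec <- function(n, seed = 1L,
                         alphabet = c("C", "N", "O", "S", "F", "Cl"),
                         size_range = c(6L, 16L), ring_prob = 0.3,
                         double_bond_prob = 0.15, sigma = 0.3) {
  stopifnot(n >= 1L, all(alphabet %in% names(.valences)),
            length(size_range) == 2L, size_range[1L] >= 1L,
            size_range[2L] >= size_range[1L],
            ring_prob >= 0, ring_prob <= 1, sigma >= 0)
  structure(list(n = as.integer(n), seed = as.integer(seed),
                 alphabet = alphabet,
                 size_range = as.integer(size_range),
                 ring_prob = ring_prob, double_bond_prob = double_bond_prob,
                 sigma = sigma),
            class = "fixture_spec")
}

# deterministic 3D spring embedding: bonded springs to `blen`, short-range
# repulsion between non-bonded atoms, fixed iteration count
.spring_coords <- function(n, bonds, blen = 1.5, iters = 80L) {
  X <- matrix(stats::rnorm(n * 3L, sd = blen), n, 3L)
  if (n == 1L) return(X * 0)
  bi <- bonds$i; bj <- bonds$j
  adj <- diag(n) > 0
  if (length(bi)) { adj[cbind(bi, bj)] <- TRUE; adj[cbind(bj, bi)] <- TRUE }
  scatter_add <- function(F, contrib, grp) {
    acc <- rowsum(contrib, grp)
    rows <- as.integer(rownames(acc))
    F[rows, ] <- F[rows, , drop = FALSE] + acc
    F
  }
  for (it in seq_len(iters)) {
    F <- matrix(0, n, 3L)
    if (length(bi)) {
      dvec <- X[bj, , drop = FALSE] - X[bi, , drop = FALSE]
      d <- sqrt(rowSums(dvec^2)) + 1e-9
      pull <- (d - blen) / d
      F <- scatter_add(F, rbind(dvec * pull, -dvec * pull), c(bi, bj))
    }
    D <- as.matrix(stats::dist(X))
    close <- which(D < 1.2 * blen & !adj, arr.ind = TRUE)  # both directions
    if (nrow(close)) {
      a <- close[, 1L]; b <- close[, 2L]
      dvec <- X[b, , drop = FALSE] - X[a, , drop = FALSE]
      d <- pmax(D[close], 1e-9)
      push <- (1.2 * blen - d) / d * 0.5
      F <- scatter_add(F, -dvec * push, a)
    }
    X <- X + 0.2 * F
  }
  X
}

#' Generate synthetic drug-like molecules
#'
#' Valence-respecting random heavy-atom trees over the requested alphabet with
#' optional small-ring closures and occasional double bonds, embedded in 3D
#' by a deterministic spring layout. Byte-identical output for a fixed spec.
#'
#' @param spec a [fixture_spec()].
#' @return list of [molecule()] with ids `SYN00001, ...` and sequential
#'   registration dates.
#' @export
gen_molecules <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  if (all(.valences[spec$alphabet] == 1) && spec$size_range[2L] > 2L)
    stop("alphabet of monovalent elements cannot form molecules of this size")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  vals <- .valences[spec$alphabet]
  poly <- spec$alphabet[vals >= 2]      # elements that can extend a chain
  sizes_avail <- spec$size_range[1L]:spec$size_range[2L]
  lapply(seq_len(spec$n), function(i) {
    n <- sizes_avail[sample.int(length(sizes_avail), 1L)]
    elements <- character(n)
    free <- integer(n)
    elements[1L] <- sample(poly, 1L)
    free[1L] <- vals[elements[1L]]
    bonds <- list()
    if (n > 1L) for (a in 2L:n) {
      open <- which(free[seq_len(a - 1L)] > 0L)
      if (!length(open)) stop("valence dead end; spec infeasible")
      parent <- if (length(open) == 1L) open else sample(open, 1L)
      # keep the chain extendable: terminal elements only when other
      # open valence remains
      remaining <- sum(free[seq_len(a - 1L)]) - 1L
      pick_from <- if (remaining == 0L && a < n) poly else spec$alphabet
      elements[a] <- sample(pick_from, 1L)
      free[a] <- vals[elements[a]] - 1L
      free[parent] <- free[parent] - 1L
      bonds[[length(bonds) + 1L]] <- c(parent, a, 1L)
    }
    bonds <- if (length(bonds)) do.call(rbind, bonds) else
      matrix(integer(), 0L, 3L)
    bonds <- data.frame(i = bonds[, 1L] %||% integer(),
                        j = bonds[, 2L] %||% integer(),
                        order = bonds[, 3L] %||% integer())
    # occasional double bonds where both ends have spare valence
    for (k in seq_len(nrow(bonds))) {
      a <- bonds$i[k]; b <- bonds$j[k]
      if (free[a] > 0L && free[b] > 0L &&
          stats::runif(1) < spec$double_bond_prob) {
        bonds$order[k] <- 2L
        free[a] <- free[a] - 1L; free[b] <- free[b] - 1L
      }
    }
    # one optional ring closure of size 3-6
    if (n >= 3L && stats::runif(1) < spec$ring_prob) {
      nbl <- rep(list(integer()), n)
      for (k in seq_len(nrow(bonds))) {
        nbl[[bonds$i[k]]] <- c(nbl[[bonds$i[k]]], bonds$j[k])
        nbl[[bonds$j[k]]] <- c(nbl[[bonds$j[k]]], bonds$i[k])
      }
      dists <- .tree_distances(nbl, n)
      cand <- which(dists >= 2L & dists <= 5L &
                    outer(free > 0L, free > 0L, "&") & upper.tri(dists),
                    arr.ind = TRUE)
      if (nrow(cand)) {
        pick <- cand[sample.int(nrow(cand), 1L), ]
        bonds <- rbind(bonds, data.frame(i = pick[1L], j = pick[2L],
                                         order = 1L))
        free[pick[1L]] <- free[pick[1L]] - 1L
        free[pick[2L]] <- free[pick[2L]] - 1L
      }
    }
    coords <- .spring_coords(n, bonds)
    molecule(sprintf("SYN%05d", i), elements, coords, bonds,
             date = as.Date("2019-01-01") + (i - 1L))
  })
}

# all-pairs shortest path lengths by BFS (small n)
.tree_distances <- function(nbl, n) {
  D <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    D[s, s] <- 0L
    queue <- s
    while (length(queue)) {
      a <- queue[1L]; queue <- queue[-1L]
      for (b in nbl[[a]]) if (D[s, b] > D[s, a] + 1L) {
        D[s, b] <- D[s, a] + 1L
        queue <- c(queue, b)
      }
    }
  }
  D
}

#' Draw a per-element contribution table
#'
#' @param alphabet element symbols.
#' @param seed seed.
#' @return named numeric vector of standard-normal contributions.
#' @export
random_contributions <- function(alphabet, seed = 1L) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  stats::setNames(stats::rnorm(length(alphabet)), alphabet)
}

#' Additive atomic-contribution property labels
#'
#' Each molecule's label is the sum over its atoms of a per-element
#' contribution, plus Gaussian noise: a ground truth a property-regression
#' model must be able to recover.
#'
#' @param mols list of [molecule()].
#' @param contributions named numeric vector covering every element present.
#' @param sigma noise standard deviation.
#' @param seed noise seed.
#' @return numeric labels, one per molecule.
#' @export
gen_additive_property <- function(mols, contributions, sigma = 0, seed = 1L) {
  missing_el <- setdiff(unique(unlist(lapply(mols, `[[`, "elements"))),
                        names(contributions))
  if (length(missing_el))
    stop("contributions missing for: ", paste(missing_el, collapse = ", "))
  base <- vapply(mols, function(m) sum(contributions[m$elements]),
                 numeric(1))
  if (sigma > 0) {
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
    set.seed(seed)
    base <- base + stats::rnorm(length(base), 0, sigma)
  }
  base
}

#' Correlated multi-task labels with controllable overlap
#'
#' Builds a label matrix whose tasks share a latent additive property:
#' every task mixes the standardized latent with its own standardized
#' idiosyncratic additive property so that the pairwise inter-task label
#' correlation (before noise) equals `rho`, then adds Gaussian noise. Task
#' `t` is labeled only for the first `sizes[t]` molecules; the rest are
#' masked, emulating endpoints assayed on different compound subsets.
#'
#' @param mols list of [molecule()].
#' @param rho target inter-task correlation; negative values are allowed
#'   only for exactly two tasks.
#' @param sizes integer vector of labeled-compound counts per task.
#' @param sigma per-task label noise standard deviation.
#' @param seed seed for contribution tables and noise.
#' @return list with `labels` (n x n_tasks, NA where masked), `mask`
#'   (logical), `latent` (the standardized latent property).
#' @export
gen_correlated_tasks <- function(mols, rho, sizes, sigma = 0.3, seed = 1L) {
  n_tasks <- length(sizes)
  stopifnot(n_tasks >= 1L, abs(rho) <= 1,
            all(sizes >= 1L), all(sizes <= length(mols)))
  if (rho < 0 && n_tasks > 2L)
    stop("negative inter-task correlation is only consistent for 2 tasks")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  zscore <- function(x) if (stats::sd(x) > 0) (x - mean(x)) / stats::sd(x)
                        else x * 0
  alphabet <- unique(unlist(lapply(mols, `[[`, "elements")))
  draw_prop <- function() {
    contrib <- stats::setNames(stats::rnorm(length(alphabet)), alphabet)
    zscore(vapply(mols, function(m) sum(contrib[m$elements]), numeric(1)))
  }
  # idiosyncratic parts are residualized against the latent and against each
  # other: two random contribution tables are far from orthogonal on the same
  # molecules (both load on composition/size), and any linear combination of
  # additive properties is itself additive, so orthogonalizing keeps every
  # task an exact additive function of the molecule while making the pairwise
  # label correlation equal rho
  basis <- list()
  draw_orthogonal <- function() {
    e <- draw_prop()
    for (u in basis) e <- e - sum(e * u) / sum(u * u) * u
    e <- zscore(e)
    basis[[length(basis) + 1L]] <<- e
    e
  }
  latent <- draw_orthogonal()
  a <- sqrt(abs(rho)); b <- sqrt(1 - abs(rho))
  labels <- matrix(NA_real_, length(mols), n_tasks,
                   dimnames = list(NULL, paste0("task", seq_len(n_tasks))))
  mask <- matrix(FALSE, length(mols), n_tasks,
                 dimnames = dimnames(labels))
  for (t in seq_len(n_tasks)) {
    sign_t <- if (rho < 0 && t == 2L) -1 else 1
    y <- sign_t * a * latent + b * draw_orthogonal() +
      stats::rnorm(length(mols), 0, sigma)
    ix <- seq_len(sizes[t])
    labels[ix, t] <- y[ix]
    mask[ix, t] <- TRUE
  }
  list(labels = labels, mask = mask, latent = latent)
}

#' Build labeled examples from molecules and labels
#'
#' @param mols list of [molecule()].
#' @param labels numeric vector (single task) or matrix (one row per
#'   molecule).
#' @param mask optional presence matrix.
#' @param config a [graph_config()].
#' @return list of [labeled_example()].
#' @export
make_examples <- function(mols, labels, mask = NULL,
                          config = graph_config()) {
  labels <- as.matrix(labels)
  if (is.null(colnames(labels)))
    colnames(labels) <- paste0("task", seq_len(ncol(labels)))
  stopifnot(nrow(labels) == length(mols))
  lapply(seq_along(mols), function(i)
    labeled_example(build_graph(mols[[i]], config),
                    stats::setNames(labels[i, ], colnames(labels)),
                    mask = if (is.null(mask)) NULL else mask[i, ],
                    date = mols[[i]]$date))
}
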