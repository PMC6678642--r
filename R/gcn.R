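#' Network architecture configuration
#'
#' Describes a graph convolutional regression network: `n_conv_layers`
#' stacked convolution filters (each transforming neighbor atom + pair
#' features to `transform_widths[k]` channels, reducing them with the
#' commutative Max/Sum/Avg operator and concatenating onto the incoming atom
#' state), Max/Sum/Avg pooling to a molecule embedding, and a LeakyReLU dense
#' head with one linear output per task. Atom-state widths follow the
#' recurrence `d[k+1] = d[k] + 3 * transform_widths[k]`.
#'
#' @param n_conv_layers number of stacked convolution filters.
#' @param transform_widths per-layer transform width (recycled to
#'   `n_conv_layers`).
#' @param head_widths hidden widths of the dense head.
#' @param n_tasks number of regression endpoints predicted jointly.
#' @param alpha LeakyReLU negative slope.
#' @param bn_momentum running-statistics update rate of the batch
#'   normalization applied to atom states after each convolution.
#' @param bn_eps batch normalization variance floor. The default (1e-3) is
#'   deliberately larger than the deep-learning convention of 1e-5: atom
#'   feature blocks contain near-constant channels (rare element one-hots,
#'   ring counts), and a tiny floor amplifies them by up to 1/sqrt(eps),
#'   destabilizing the eval-time use of running statistics.
#' @param seed seed for weight initialization.
#' @param task_names optional endpoint names.
#' @param graph a [graph_config()] describing the expected featurization.
#' @return list of class `network_config`.
#' @export
network_config <- function(n_conv_layers = 3L, transform_widths = 64L,
                           head_widths = c(256L, 128L), n_tasks = 1L,
                           alpha = 0.01, bn_momentum = 0.1, bn_eps = 1e-3,
                           seed = 42L, task_names = NULL,
                           graph = graph_config()) {
  transform_widths <- rep_len(as.integer(transform_widths), n_conv_layers)
  stopifnot(n_conv_layers >= 0L, all(transform_widths > 0L),
            all(head_widths > 0L), n_tasks >= 1L, alpha > 0, alpha < 1)
  if (is.null(task_names)) task_names <- paste0("task", seq_len(n_tasks))
  stopifnot(length(task_names) == n_tasks)
  structure(list(n_conv_layers = as.integer(n_conv_layers),
                 transform_widths = transform_widths,
                 head_widths = as.integer(head_widths),
                 n_tasks = as.integer(n_tasks), alpha = alpha,
                 bn_momentum = bn_momentum, bn_eps = bn_eps,
                 seed = as.integer(seed), task_names = task_names,
                 graph = graph),
            class = "network_config")
}

# atom-state width entering each layer (and the final width, last element)
conv_widths <- function(config) {
  d <- atom_feature_width()
  widths <- d
  for (t in config$transform_widths) {
    d <- d + 3L * t
    widths <- c(widths, d)
  }
  widths
}

.he_uniform <- function(nrow, ncol) {
  lim <- sqrt(6 / ncol)   # fan-in = ncol (weights act as x %*% t(W))
  matrix(stats::runif(nrow * ncol, -lim, lim), nrow, ncol)
}

#' Initialize a graph convolutional network
#'
#' Allocates convolution, batch-norm and dense-head parameters with He-style
#' uniform fan-in initialization, seeded from `config$seed`.
#'
#' @param config a [network_config()].
#' @return object of class `gcn_model`: list with `config`, flat named
#'   parameter list `params`, and batch-norm running statistics `bn`.
#' @export
gcn_init <- function(config) {
  stopifnot(inherits(config, "network_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  widths <- conv_widths(config)
  params <- list()
  bn <- list()
  for (k in seq_len(config$n_conv_layers)) {
    d_in <- widths[k] + pair_feature_width()
    d_t <- config$transform_widths[k]
    d_out <- widths[k + 1L]
    params[[paste0("conv", k, ".W")]] <- .he_uniform(d_t, d_in)
    params[[paste0("conv", k, ".b")]] <- numeric(d_t)
    params[[paste0("conv", k, ".gamma")]] <- rep(1, d_out)
    params[[paste0("conv", k, ".beta")]] <- numeric(d_out)
    bn[[k]] <- list(mean = numeric(d_out), var = rep(1, d_out))
  }
  hw <- c(3L * widths[length(widths)], config$head_widths, config$n_tasks)
  for (j in seq_len(length(hw) - 1L)) {
    params[[paste0("head", j, ".W")]] <- .he_uniform(hw[j + 1L], hw[j])
    params[[paste0("head", j, ".b")]] <- numeric(hw[j + 1L])
  }
  structure(list(config = config, params = params, bn = bn),
            class = "gcn_model")
}

#' @export
print.gcn_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(paste0("<gcn_model: %d conv layers (widths %s), head [%s], ",
                     "%d task(s), %d parameters>\n"),
              cfg$n_conv_layers,
              paste(cfg$transform_widths, collapse = ","),
              paste(cfg$head_widths, collapse = ","), cfg$n_tasks,
              sum(vapply(x$params, length, integer(1)))))
  invisible(x)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Pack feature graphs into one flat batch
#'
#' Concatenates graphs into the flat arrays the vectorized forward pass
#' consumes: a stacked atom-feature matrix with per-atom molecule segment
#' ids, and globally re-indexed neighbor edges. Unpacking by segment id
#' recovers each molecule's graph exactly.
#'
#' @param graphs list of [build_graph()] results.
#' @param labels optional numeric matrix (one row per molecule) of task
#'   labels.
#' @param mask optional logical matrix of label presence flags.
#' @return object of class `packed_batch`.
#' @export
pack_graphs <- function(graphs, labels = NULL, mask = NULL) {
  stopifnot(length(graphs) >= 1L)
  n_atoms <- vapply(graphs, function(g) g$n_atoms, integer(1))
  offset <- c(0L, cumsum(n_atoms))
  A <- do.call(rbind, lapply(graphs, function(g) g$atom_features))
  mol_id <- rep.int(seq_along(graphs), n_atoms)
  center <- unlist(lapply(seq_along(graphs), function(i)
    graphs[[i]]$edges$center + offset[i]), use.names = FALSE)
  nbr <- unlist(lapply(seq_along(graphs), function(i)
    graphs[[i]]$edges$nbr + offset[i]), use.names = FALSE)
  pair <- do.call(rbind, lapply(graphs, function(g) g$edges$pair))
  if (is.null(center)) { center <- integer(); nbr <- integer() }
  if (is.null(pair)) pair <- matrix(0, 0L, pair_feature_width())
  if (!is.null(labels)) {
    labels <- as.matrix(labels)
    stopifnot(nrow(labels) == length(graphs))
    if (is.null(mask)) mask <- !is.na(labels)
    mask <- as.matrix(mask)
  }
  structure(list(A = A, mol_id = mol_id, n_mol = length(graphs),
                 n_atoms = sum(n_atoms), center = as.integer(center),
                 nbr = as.integer(nbr), pair = pair, labels = labels,
                 mask = mask,
                 ids = vapply(graphs, function(g) g$id, character(1))),
            class = "packed_batch")
}

#' Transform one neighbor's features through a convolution filter
#'
#' Computes `f(W %*% concat(A_b, P_ab) + b)`: the shared-weight affine map
#' plus LeakyReLU applied to the concatenation of a neighbor atom state and
#' the pair features, the elementary step of the convolution operator.
#'
#' @param A_b neighbor atom state (vector, or matrix with one state per row).
#' @param P_ab pair feature vector (or matrix of rows matching `A_b`).
#' @param W weight matrix (d_transform x (d_state + 5)).
#' @param b bias vector (d_transform).
#' @param alpha LeakyReLU negative slope.
#' @return transformed state(s), same orientation as the input.
#' @export
conv_transform <- function(A_b, P_ab, W, b, alpha = 0.01) {
  vec <- is.null(dim(A_b))
  A_b <- rbind(A_b); P_ab <- rbind(P_ab)
  Z <- cbind(A_b, P_ab)
  if (ncol(Z) != ncol(W)) stop("state/pair width does not match W")
  if (nrow(W) != length(b)) stop("bias length does not match W")
  out <- leaky_relu(sweep(Z %*% t(W), 2L, b, "+"), alpha)
  if (vec) drop(out) else out
}

# batch norm forward. mode "train" normalizes with batch statistics and
# returns updated running stats; "eval" uses the stored running stats.
.bn_forward <- function(X, gamma, beta, state, mode, momentum, eps) {
  if (mode == "train") {
    mu <- colMeans(X)
    v <- colMeans(X^2) - mu^2
    v <- pmax(v, 0)
    state$mean <- (1 - momentum) * state$mean + momentum * mu
    state$var <- (1 - momentum) * state$var + momentum * v
  } else {
    mu <- state$mean
    v <- state$var
  }
  ivar <- 1 / sqrt(v + eps)
  xhat <- sweep(sweep(X, 2L, mu, "-"), 2L, ivar, "*")
  Y <- sweep(sweep(xhat, 2L, gamma, "*"), 2L, beta, "+")
  list(Y = Y, xhat = xhat, ivar = ivar, mu = mu, state = state, mode = mode)
}

.bn_backward <- function(dY, cache, gamma) {
  N <- nrow(cache$xhat)
  dgamma <- colSums(dY * cache$xhat)
  dbeta <- colSums(dY)
  dxhat <- sweep(dY, 2L, gamma, "*")
  if (cache$mode == "train") {
    # standard batch-norm gradient through the batch statistics
    t1 <- sweep(dxhat, 2L, colSums(dxhat) / N, "-")
    t2 <- sweep(cache$xhat, 2L, colSums(dxhat * cache$xhat) / N, "*")
    dX <- sweep(t1 - t2, 2L, cache$ivar, "*")
  } else {
    dX <- sweep(dxhat, 2L, cache$ivar, "*")
  }
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

#' Forward pass of the network
#'
#' Runs stacked convolution filters, Max/Sum/Avg pooling and the dense head
#' on a packed batch. In `"train"` mode batch normalization uses batch
#' statistics and updates the running averages (returned via the `model`
#' element); in `"eval"` mode it uses the stored running statistics, making
#' predictions deterministic and independent of how molecules are batched.
#'
#' @param model a [gcn_init()] model.
#' @param batch a [pack_graphs()] batch.
#' @param mode `"eval"` or `"train"`.
#' @param keep_cache keep intermediate activations for the backward pass.
#' @return list with `pred` (n_mol x n_tasks), `emb` (molecule embeddings),
#'   `model` (with updated batch-norm state in train mode) and, if requested,
#'   `cache`.
#' @export
gcn_forward <- function(model, batch, mode = c("eval", "train"),
                        keep_cache = FALSE) {
  mode <- match.arg(mode)
  cfg <- model$config
  p <- model$params
  A <- batch$A
  caches <- list()
  for (k in seq_len(cfg$n_conv_layers)) {
    W <- p[[paste0("conv", k, ".W")]]
    b <- p[[paste0("conv", k, ".b")]]
    if (length(batch$center)) {
      Z <- cbind(A[batch$nbr, , drop = FALSE], batch$pair)
      U <- sweep(Z %*% t(W), 2L, b, "+")
      Tm <- leaky_relu(U, cfg$alpha)
      red <- segment_reduce(Tm, batch$center, batch$n_atoms)
    } else {
      Z <- matrix(0, 0L, ncol(W)); U <- matrix(0, 0L, nrow(W)); Tm <- U
      red <- segment_reduce(U, integer(), batch$n_atoms)
    }
    R <- cbind(red$max, red$sum, red$avg)
    C <- cbind(A, R)
    bnc <- .bn_forward(C, p[[paste0("conv", k, ".gamma")]],
                       p[[paste0("conv", k, ".beta")]], model$bn[[k]],
                       mode, cfg$bn_momentum, cfg$bn_eps)
    model$bn[[k]] <- bnc$state
    if (keep_cache)
      caches[[k]] <- list(A_in = A, Z = Z, U = U, red = red,
                          bn = bnc[c("xhat", "ivar", "mu", "mode")])
    A <- bnc$Y
  }
  pool_red <- segment_reduce(A, batch$mol_id, batch$n_mol)
  emb <- cbind(pool_red$max, pool_red$sum, pool_red$avg)
  H <- emb
  n_head <- sum(grepl("^head[0-9]+\\.W$", names(p)))
  head_cache <- list()
  for (j in seq_len(n_head)) {
    W <- p[[paste0("head", j, ".W")]]
    b <- p[[paste0("head", j, ".b")]]
    Zh <- sweep(H %*% t(W), 2L, b, "+")
    if (keep_cache) head_cache[[j]] <- list(H_in = H, Z = Zh)
    H <- if (j < n_head) leaky_relu(Zh, cfg$alpha) else Zh
  }
  pred <- H
  colnames(pred) <- cfg$task_names
  out <- list(pred = pred, emb = emb, model = model)
  if (keep_cache)
    out$cache <- list(conv = caches, pool = pool_red, head = head_cache,
                      A_final = A, batch = batch)
  out
}

#' Pool atom states to a molecule embedding
#'
#' Applies the commutative Max/Sum/Avg reduction over the atom-state rows of
#' one molecule, producing the fixed-length embedding regardless of atom
#' count or order.
#'
#' @param states numeric matrix of per-atom states (>= 1 row).
#' @return numeric vector of length `3 * ncol(states)`.
#' @export
pool_atoms <- function(states) {
  states <- as.matrix(states)
  if (nrow(states) < 1L) stop("cannot pool an empty molecule")
  commutative_reduce(states)
}

#' Run the dense head alone
#'
#' @param embedding molecule embedding vector (or matrix of rows).
#' @param model a `gcn_model` (its head parameters are used).
#' @return prediction vector/matrix, one column per task.
#' @export
dense_head <- function(embedding, model) {
  vec <- is.null(dim(embedding))
  H <- rbind(embedding)
  p <- model$params
  n_head <- sum(grepl("^head[0-9]+\\.W$", names(p)))
  for (j in seq_len(n_head)) {
    W <- p[[paste0("head", j, ".W")]]
    b <- p[[paste0("head", j, ".b")]]
    if (ncol(H) != ncol(W)) stop("embedding width does not match head")
    H <- sweep(H %*% t(W), 2L, b, "+")
    if (j < n_head) H <- leaky_relu(H, model$config$alpha)
  }
  if (vec) drop(H) else H
}

#' Predict properties for molecules or graphs
#'
#' Convenience eval-mode forward: accepts molecules (featurized on the fly)
#' or prebuilt graphs and returns per-task predictions, optionally with
#' embeddings.
#'
#' @param object a `gcn_model`.
#' @param newdata list of [molecule()] or `mol_graph` objects (or a single
#'   one).
#' @param embeddings also return molecule embeddings.
#' @param ... unused.
#' @return data.frame of predictions (and attribute `"embeddings"` when
#'   requested).
#' @export
predict.gcn_model <- function(object, newdata, embeddings = FALSE, ...) {
  if (inherits(newdata, c("molecule", "mol_graph"))) newdata <- list(newdata)
  graphs <- lapply(newdata, function(x)
    if (inherits(x, "mol_graph")) x else build_graph(x, object$config$graph))
  fwd <- gcn_forward(object, pack_graphs(graphs), mode = "eval")
  out <- as.data.frame(fwd$pred)
  rownames(out) <- vapply(graphs, function(g) g$id, character(1))
  if (embeddings) attr(out, "embeddings") <- fwd$emb
  out
}
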