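# Reverse-mode gradients for the packed forward pass. The cache produced by
# gcn_forward(keep_cache = TRUE) holds every intermediate needed; gradients
# come back as a flat named list parallel to model$params.

gcn_backward <- function(model, cache, dPred) {
  cfg <- model$config
  p <- model$params
  grads <- lapply(p, function(x) array(0, dim = dim(x) %||% length(x)))
  batch <- cache$batch

  # dense head
  n_head <- length(cache$head)
  dH <- dPred
  for (j in rev(seq_len(n_head))) {
    hc <- cache$head[[j]]
    W <- p[[paste0("head", j, ".W")]]
    dZ <- if (j < n_head) dH * .leaky_relu_grad(hc$Z, cfg$alpha) else dH
    grads[[paste0("head", j, ".W")]] <- unname(t(dZ) %*% hc$H_in)
    grads[[paste0("head", j, ".b")]] <- unname(colSums(dZ))
    dH <- dZ %*% W
  }

  # pooling
  dA <- segment_reduce_backward(dH, cache$pool, batch$mol_id,
                                nrow(cache$A_final))

  # conv stack, reversed
  for (k in rev(seq_len(cfg$n_conv_layers))) {
    cc <- cache$conv[[k]]
    gamma <- p[[paste0("conv", k, ".gamma")]]
    bnb <- .bn_backward(dA, cc$bn, gamma)
    grads[[paste0("conv", k, ".gamma")]] <- unname(bnb$dgamma)
    grads[[paste0("conv", k, ".beta")]] <- unname(bnb$dbeta)
    dC <- bnb$dX
    d_in <- ncol(cc$A_in)
    dA <- dC[, seq_len(d_in), drop = FALSE]
    dR <- dC[, -seq_len(d_in), drop = FALSE]
    if (length(batch$center)) {
      dT <- segment_reduce_backward(dR, cc$red, batch$center, nrow(cc$U))
      dU <- dT * .leaky_relu_grad(cc$U, cfg$alpha)
      W <- p[[paste0("conv", k, ".W")]]
      grads[[paste0("conv", k, ".W")]] <- unname(t(dU) %*% cc$Z)
      grads[[paste0("conv", k, ".b")]] <- unname(colSums(dU))
      dZ <- dU %*% W
      dA_nbr <- dZ[, seq_len(d_in), drop = FALSE]
      acc <- rowsum(dA_nbr, batch$nbr)
      rows <- as.integer(rownames(acc))
      dA[rows, ] <- dA[rows, , drop = FALSE] + acc
    }
  }
  grads
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Apply one convolution filter to a single molecule
#'
#' Exposes the per-layer update outside the packed training path: every
#' neighbor of each atom is transformed with [conv_transform()], the
#' transforms are reduced with the commutative Max/Sum/Avg operator (atoms
#' without neighbors receive the zero block), the reduction is concatenated
#' onto the incoming state, and the result is batch-normalized.
#'
#' @param states numeric matrix of per-atom states (n x d).
#' @param graph a [build_graph()] result for the same molecule.
#' @param W,b,gamma,beta layer parameters; `gamma`/`beta` default to the
#'   identity normalization.
#' @param bn_state running batch-norm statistics (list with `mean`, `var`);
#'   defaults to mean 0 / variance 1.
#' @param mode `"eval"` (running statistics) or `"train"` (batch statistics).
#' @param alpha,bn_eps,bn_momentum numeric settings as in [network_config()].
#' @return list with `states` (n x (d + 3*nrow(W))) and updated `bn_state`.
#' @export
conv_layer <- function(states, graph, W, b, gamma = NULL, beta = NULL,
                       bn_state = NULL, mode = c("eval", "train"),
                       alpha = 0.01, bn_eps = 1e-3, bn_momentum = 0.1) {
  mode <- match.arg(mode)
  states <- as.matrix(states)
  if (ncol(states) + pair_feature_width() != ncol(W))
    stop("state width does not match W")
  n <- nrow(states)
  d_t <- nrow(W)
  d_out <- ncol(states) + 3L * d_t
  if (is.null(gamma)) gamma <- rep(1, d_out)
  if (is.null(beta)) beta <- numeric(d_out)
  if (is.null(bn_state)) bn_state <- list(mean = numeric(d_out),
                                          var = rep(1, d_out))
  if (length(graph$edges$center)) {
    Tm <- conv_transform(states[graph$edges$nbr, , drop = FALSE],
                         graph$edges$pair, W, b, alpha)
    red <- segment_reduce(rbind(Tm), graph$edges$center, n)
  } else {
    red <- segment_reduce(matrix(0, 0L, d_t), integer(), n)
  }
  C <- cbind(states, red$max, red$sum, red$avg)
  bnc <- .bn_forward(C, gamma, beta, bn_state, mode, bn_momentum, bn_eps)
  list(states = bnc$Y, bn_state = bnc$state)
}
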