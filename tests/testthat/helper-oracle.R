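# Independent naive-loop reimplementation of the eval-mode forward pass,
# written with explicit scalar loops and no shared code with the package
# internals. Used to pin down the convolution algebra on tiny molecules.

naive_leaky <- function(x, alpha = 0.01) {
  out <- numeric(length(x))
  for (i in seq_along(x)) out[i] <- if (x[i] > 0) x[i] else alpha * x[i]
  out
}

naive_affine <- function(W, x, b) {
  out <- numeric(nrow(W))
  for (r in seq_len(nrow(W))) {
    acc <- b[r]
    for (c in seq_len(ncol(W))) acc <- acc + W[r, c] * x[c]
    out[r] <- acc
  }
  out
}

naive_reduce <- function(vecs, width) {
  if (!length(vecs)) return(numeric(3 * width))
  mx <- rep(-Inf, width); sm <- numeric(width)
  for (v in vecs) for (j in seq_len(width)) {
    if (v[j] > mx[j]) mx[j] <- v[j]
    sm[j] <- sm[j] + v[j]
  }
  c(mx, sm, sm / length(vecs))
}

# eval-mode forward on one graph, given a gcn_model
naive_forward <- function(model, graph) {
  cfg <- model$config
  A <- graph$atom_features
  n <- nrow(A)
  for (k in seq_len(cfg$n_conv_layers)) {
    W <- model$params[[paste0("conv", k, ".W")]]
    b <- model$params[[paste0("conv", k, ".b")]]
    d_t <- nrow(W)
    newA <- NULL
    for (a in seq_len(n)) {
      transforms <- list()
      for (e in seq_along(graph$edges$center)) {
        if (graph$edges$center[e] == a) {
          nb <- graph$edges$nbr[e]
          x <- c(A[nb, ], graph$edges$pair[e, ])
          transforms[[length(transforms) + 1]] <-
            naive_leaky(naive_affine(W, x, b), cfg$alpha)
        }
      }
      row <- c(A[a, ], naive_reduce(transforms, d_t))
      newA <- rbind(newA, row)
    }
    # eval-mode batch norm with the stored running statistics
    gamma <- model$params[[paste0("conv", k, ".gamma")]]
    beta <- model$params[[paste0("conv", k, ".beta")]]
    st <- model$bn[[k]]
    for (a in seq_len(n)) for (j in seq_len(ncol(newA)))
      newA[a, j] <- gamma[j] * (newA[a, j] - st$mean[j]) /
        sqrt(st$var[j] + cfg$bn_eps) + beta[j]
    A <- newA
  }
  rows <- lapply(seq_len(n), function(a) A[a, ])
  emb <- naive_reduce(rows, ncol(A))
  H <- emb
  n_head <- sum(grepl("^head[0-9]+\\.W$", names(model$params)))
  for (j in seq_len(n_head)) {
    W <- model$params[[paste0("head", j, ".W")]]
    b <- model$params[[paste0("head", j, ".b")]]
    H <- naive_affine(W, H, b)
    if (j < n_head) H <- naive_leaky(H, cfg$alpha)
  }
  H
}

# fill a model with seeded random parameters (including batch-norm stats)
randomize_model <- function(model, seed = 1) {
  set.seed(seed)
  for (nm in names(model$params)) {
    p <- model$params[[nm]]
    model$params[[nm]][] <- rnorm(length(p), sd = 0.5)
  }
  for (k in seq_along(model$bn)) {
    model$bn[[k]]$mean[] <- rnorm(length(model$bn[[k]]$mean), sd = 0.3)
    model$bn[[k]]$var[] <- runif(length(model$bn[[k]]$var), 0.5, 2)
  }
  model
}
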