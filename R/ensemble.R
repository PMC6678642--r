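#' A candidate entry for the model pool
#'
#' @param model a trained `gcn_model`.
#' @param score validation score, higher is better (e.g. validation R^2 or
#'   negative validation loss); must be finite.
#' @param tag configuration tag (string).
#' @param epoch epoch the snapshot was taken at.
#' @return list of class `pool_entry`.
#' @export
pool_entry <- function(model, score, tag = "cfg", epoch = 1L) {
  stopifnot(is.finite(score))
  structure(list(model = model, score = score, tag = as.character(tag),
                 epoch = as.integer(epoch)), class = "pool_entry")
}

#' Train a pool of candidate models
#'
#' Trains one model per network configuration and records each best epoch as
#' a pool entry scored by negative validation loss.
#'
#' @param examples list of [labeled_example()].
#' @param configs list of [network_config()].
#' @param config a [train_config()].
#' @return list of [pool_entry()].
#' @export
train_model_pool <- function(examples, configs, config = train_config()) {
  lapply(seq_along(configs), function(i) {
    fit <- train_gcn(examples, configs[[i]], config)
    score <- -fit$history$val_loss[fit$best_epoch]
    if (!length(score) || !is.finite(score))
      score <- -fit$history$train_loss[nrow(fit$history)]
    pool_entry(fit$model, score, tag = sprintf("cfg%d", i),
               epoch = fit$best_epoch)
  })
}

#' Select the best models from a pool
#'
#' Picks the `k` entries with the highest validation score; ties are broken
#' by earlier epoch, then by configuration tag.
#'
#' @param pool list of [pool_entry()].
#' @param k number of models to keep.
#' @return list of `pool_entry`, best first.
#' @export
select_models <- function(pool, k) {
  stopifnot(length(pool) >= 1L)
  if (k <= 0L) stop("k must be positive")
  if (k > length(pool)) {
    warning(sprintf("k = %d exceeds pool size %d; returning the whole pool",
                    k, length(pool)))
    k <- length(pool)
  }
  scores <- vapply(pool, function(e) e$score, numeric(1))
  epochs <- vapply(pool, function(e) e$epoch, integer(1))
  tags <- vapply(pool, function(e) e$tag, character(1))
  pool[order(-scores, epochs, tags)[seq_len(k)]]
}

#' Initialize an ensemble fine-tuning model
#'
#' Builds the second-stage model over frozen base models: each base model's
#' concatenated (embedding, predictions) vector passes through its own affine
#' + LeakyReLU encoder to a common width, the encoded vectors are reduced
#' order-invariantly with the commutative Max/Sum/Avg operator, optionally
#' concatenated with an explicit descriptor vector, and a dense head maps the
#' result to the final predictions.
#'
#' @param members list of `pool_entry` (or bare `gcn_model`s).
#' @param enc_width encoder output width per base model.
#' @param head_widths hidden widths of the fine-tuning head.
#' @param explicit_width width of the optional explicit feature vector
#'   (0 = none).
#' @param alpha LeakyReLU slope.
#' @param seed initialization seed.
#' @return object of class `ensemble_model`.
#' @export
ensemble_init <- function(members, enc_width = 64L, head_widths = 64L,
                          explicit_width = 0L, alpha = 0.01, seed = 42L) {
  stopifnot(length(members) >= 1L)
  members <- lapply(members, function(m)
    if (inherits(m, "pool_entry")) m$model else m)
  n_tasks <- members[[1L]]$config$n_tasks
  stopifnot(all(vapply(members, function(m) m$config$n_tasks, integer(1))
                == n_tasks))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  enc <- lapply(members, function(m) {
    d_in <- 3L * conv_widths(m$config)[m$config$n_conv_layers + 1L] + n_tasks
    list(W = .he_uniform(enc_width, d_in), b = numeric(enc_width))
  })
  hw <- c(3L * enc_width + explicit_width, head_widths, n_tasks)
  head <- lapply(seq_len(length(hw) - 1L), function(j)
    list(W = .he_uniform(hw[j + 1L], hw[j]), b = numeric(hw[j + 1L])))
  structure(list(members = members, enc = enc, head = head,
                 enc_width = as.integer(enc_width),
                 explicit_width = as.integer(explicit_width),
                 n_tasks = n_tasks, alpha = alpha,
                 task_names = members[[1L]]$config$task_names),
            class = "ensemble_model")
}

#' @export
print.ensemble_model <- function(x, ...) {
  cat(sprintf("<ensemble_model: %d base models, encoder width %d, %d task(s)>\n",
              length(x$members), x$enc_width, x$n_tasks))
  invisible(x)
}

# eval-mode (embedding, prediction) feature matrix of one base model
.member_features <- function(model, batch) {
  fwd <- gcn_forward(model, batch, mode = "eval")
  cbind(fwd$emb, fwd$pred)
}

# core forward over precomputed member feature matrices
.ens_forward_feats <- function(ens, feats, explicit = NULL,
                               keep_cache = FALSE) {
  k <- length(feats)
  n <- nrow(feats[[1L]])
  h <- ens$enc_width
  Zpre <- vector("list", k)
  Zact <- vector("list", k)
  MX <- matrix(-Inf, n, h); AMX <- matrix(NA_integer_, n, h)
  S <- matrix(0, n, h)
  for (m in seq_len(k)) {
    Zpre[[m]] <- sweep(feats[[m]] %*% t(ens$enc[[m]]$W), 2L,
                       ens$enc[[m]]$b, "+")
    Zact[[m]] <- leaky_relu(Zpre[[m]], ens$alpha)
    S <- S + Zact[[m]]
    upd <- Zact[[m]] > MX
    MX[upd] <- Zact[[m]][upd]
    AMX[upd] <- m
  }
  R <- cbind(MX, S, S / k)
  H <- if (!is.null(explicit)) cbind(R, explicit) else R
  head_cache <- vector("list", length(ens$head))
  for (j in seq_along(ens$head)) {
    Zh <- sweep(H %*% t(ens$head[[j]]$W), 2L, ens$head[[j]]$b, "+")
    if (keep_cache) head_cache[[j]] <- list(H_in = H, Z = Zh)
    H <- if (j < length(ens$head)) leaky_relu(Zh, ens$alpha) else Zh
  }
  out <- list(pred = H)
  if (keep_cache)
    out$cache <- list(Zpre = Zpre, Zact = Zact, argmax = AMX, k = k,
                      feats = feats, head = head_cache,
                      has_explicit = !is.null(explicit))
  out
}

#' Ensemble forward pass
#'
#' Scores molecules with the fine-tuned ensemble: each frozen base model
#' produces embeddings and predictions, which are encoded, reduced
#' order-invariantly across models and passed through the fine-tuning head.
#' The output does not depend on the order of the base models.
#'
#' @param ens an [ensemble_init()] model.
#' @param graphs list of `mol_graph` (or [molecule()]) objects, or a
#'   `packed_batch`.
#' @param explicit optional numeric matrix of explicit descriptors, one row
#'   per molecule, width `ens$explicit_width`.
#' @return numeric matrix of predictions (n x n_tasks).
#' @export
ensemble_forward <- function(ens, graphs, explicit = NULL) {
  batch <- if (inherits(graphs, "packed_batch")) graphs else {
    if (inherits(graphs, c("molecule", "mol_graph"))) graphs <- list(graphs)
    graphs <- lapply(graphs, function(x)
      if (inherits(x, "mol_graph")) x
      else build_graph(x, ens$members[[1L]]$config$graph))
    pack_graphs(graphs)
  }
  if (!is.null(explicit)) {
    explicit <- as.matrix(explicit)
    if (ncol(explicit) != ens$explicit_width)
      stop(sprintf("explicit feature width %d does not match the ensemble (%d)",
                   ncol(explicit), ens$explicit_width))
  } else if (ens$explicit_width > 0L) {
    stop("this ensemble requires an explicit feature matrix")
  }
  feats <- lapply(ens$members, .member_features, batch = batch)
  pred <- .ens_forward_feats(ens, feats, explicit)$pred
  colnames(pred) <- ens$task_names
  pred
}

# gradients of the ensemble parameters given upstream dPred
.ens_backward <- function(ens, cache, dPred) {
  genc <- lapply(ens$enc, function(e) list(W = e$W * 0, b = e$b * 0))
  ghead <- lapply(ens$head, function(hh) list(W = hh$W * 0, b = hh$b * 0))
  dH <- dPred
  for (j in rev(seq_along(ens$head))) {
    hc <- cache$head[[j]]
    dZ <- if (j < length(ens$head)) dH * .leaky_relu_grad(hc$Z, ens$alpha)
          else dH
    ghead[[j]]$W <- unname(t(dZ) %*% hc$H_in)
    ghead[[j]]$b <- unname(colSums(dZ))
    dH <- dZ %*% ens$head[[j]]$W
  }
  h <- ens$enc_width
  dR <- dH[, seq_len(3L * h), drop = FALSE]     # explicit block carries no params
  dMX <- dR[, seq_len(h), drop = FALSE]
  dS <- dR[, h + seq_len(h), drop = FALSE]
  dAvg <- dR[, 2L * h + seq_len(h), drop = FALSE]
  base <- dS + dAvg / cache$k
  for (m in seq_len(cache$k)) {
    dZact <- base + dMX * (cache$argmax == m)
    dZ <- dZact * .leaky_relu_grad(cache$Zpre[[m]], ens$alpha)
    genc[[m]]$W <- unname(t(dZ) %*% cache$feats[[m]])
    genc[[m]]$b <- unname(colSums(dZ))
  }
  list(enc = genc, head = ghead)
}

#' Fine-tune an ensemble over selected base models
#'
#' Trains only the ensemble parameters (encoders and head) with Adam on the
#' masked multi-task loss; the base models stay frozen, so their embeddings
#' and predictions are computed once up front. Validation follows the same
#' chronological hold-out and early stopping as [train_gcn()].
#'
#' @param selected list of [pool_entry()] (e.g. from [select_models()]).
#' @param examples list of [labeled_example()].
#' @param config a [train_config()] (the atom budget is ignored: features are
#'   precomputed).
#' @param enc_width,head_widths,explicit_width,seed passed to
#'   [ensemble_init()].
#' @param explicit optional explicit descriptor matrix, one row per example.
#' @return list of class `ensemble_fit` with `model` (best epoch ensemble)
#'   and `history`.
#' @export
finetune_train <- function(selected, examples, config = train_config(),
                           enc_width = 64L, head_widths = 64L,
                           explicit_width = 0L, explicit = NULL,
                           seed = 42L) {
  ens <- ensemble_init(selected, enc_width, head_widths, explicit_width,
                       seed = seed)
  n <- length(examples)
  labels <- do.call(rbind, lapply(examples, function(e) e$labels))
  mask <- do.call(rbind, lapply(examples, function(e) e$mask))
  weights <- config$weights %||% rep(1, ens$n_tasks)
  batch <- examples_batch(examples)
  feats <- lapply(ens$members, .member_features, batch = batch)
  if (config$val_fraction > 0) {
    dates <- vapply(examples, function(e)
      if (is.null(e$date)) NA_real_ else as.numeric(e$date), numeric(1))
    ord <- if (all(is.na(dates))) seq_len(n) else order(dates, seq_len(n))
    n_val <- max(1L, round(n * config$val_fraction))
    val_ix <- ord[(n - n_val + 1L):n]
  } else val_ix <- integer()
  fit_ix <- setdiff(seq_len(n), val_ix)
  sub <- function(M, ix) M[ix, , drop = FALSE]
  feats_fit <- lapply(feats, sub, ix = fit_ix)
  feats_val <- lapply(feats, sub, ix = val_ix)
  expl_fit <- if (!is.null(explicit)) sub(as.matrix(explicit), fit_ix)
  expl_val <- if (!is.null(explicit)) sub(as.matrix(explicit), val_ix)

  flat <- function(e) {                      # flatten for the Adam updater
    out <- list()
    for (m in seq_along(e$enc)) {
      out[[paste0("enc", m, ".W")]] <- e$enc[[m]]$W
      out[[paste0("enc", m, ".b")]] <- e$enc[[m]]$b
    }
    for (j in seq_along(e$head)) {
      out[[paste0("fthead", j, ".W")]] <- e$head[[j]]$W
      out[[paste0("fthead", j, ".b")]] <- e$head[[j]]$b
    }
    out
  }
  unflat <- function(e, fl) {
    for (m in seq_along(e$enc)) {
      e$enc[[m]]$W <- fl[[paste0("enc", m, ".W")]]
      e$enc[[m]]$b <- fl[[paste0("enc", m, ".b")]]
    }
    for (j in seq_along(e$head)) {
      e$head[[j]]$W <- fl[[paste0("fthead", j, ".W")]]
      e$head[[j]]$b <- fl[[paste0("fthead", j, ".b")]]
    }
    e
  }
  params <- flat(ens)
  opt <- .adam_init(params)
  best <- list(loss = Inf, params = params, epoch = 0L)
  stall <- 0L
  hist <- list()
  for (epoch in seq_len(config$epochs)) {
    ens <- unflat(ens, params)
    fwd <- .ens_forward_feats(ens, feats_fit, expl_fit, keep_cache = TRUE)
    loss <- mt_loss(fwd$pred, sub(labels, fit_ix), sub(mask, fit_ix), weights)
    if (!is.finite(loss))
      stop(sprintf("fine-tuning diverged (loss %g) at epoch %d", loss, epoch))
    g <- .ens_backward(ens, fwd$cache,
                       .mt_loss_grad(fwd$pred, sub(labels, fit_ix),
                                     sub(mask, fit_ix), weights))
    gflat <- list()
    for (m in seq_along(g$enc)) {
      gflat[[paste0("enc", m, ".W")]] <- g$enc[[m]]$W
      gflat[[paste0("enc", m, ".b")]] <- g$enc[[m]]$b
    }
    for (j in seq_along(g$head)) {
      gflat[[paste0("fthead", j, ".W")]] <- g$head[[j]]$W
      gflat[[paste0("fthead", j, ".b")]] <- g$head[[j]]$b
    }
    step <- .adam_step(params, gflat, opt, config)
    params <- step$params; opt <- step$state
    row <- data.frame(epoch = epoch, train_loss = as.numeric(loss),
                      val_loss = NA_real_)
    if (length(val_ix)) {
      vp <- .ens_forward_feats(unflat(ens, params), feats_val, expl_val)$pred
      row$val_loss <- as.numeric(mt_loss(vp, sub(labels, val_ix),
                                         sub(mask, val_ix), weights))
      if (row$val_loss < best$loss) {
        best <- list(loss = row$val_loss, params = params, epoch = epoch)
        stall <- 0L
      } else stall <- stall + 1L
    } else best <- list(loss = row$train_loss, params = params, epoch = epoch)
    hist[[epoch]] <- row
    if (length(val_ix) && stall >= config$patience) break
  }
  structure(list(model = unflat(ens, best$params),
                 history = do.call(rbind, hist), best_epoch = best$epoch),
            class = "ensemble_fit")
}
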