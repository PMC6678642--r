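#' Endpoint (task) specification
#'
#' @param name endpoint name (matches a label column).
#' @param transform value transform applied at ingestion: `"none"`,
#'   `"log10"` or `"logit"`.
#' @param weight nonnegative task weight in the summed multi-task loss.
#' @return list of class `task_spec`.
#' @export
task_spec <- function(name, transform = c("none", "log10", "logit"),
                      weight = 1) {
  transform <- match.arg(transform)
  stopifnot(nzchar(name), weight >= 0)
  structure(list(name = name, transform = transform, weight = weight),
            class = "task_spec")
}

#' A labeled training example
#'
#' @param graph a [build_graph()] result.
#' @param labels named numeric vector of endpoint values (NA = absent).
#' @param mask optional logical presence flags (defaults to `!is.na(labels)`).
#' @param date optional registration date.
#' @return list of class `labeled_example`.
#' @export
labeled_example <- function(graph, labels, mask = NULL, date = NULL) {
  if (is.null(mask)) mask <- !is.na(labels)
  stopifnot(length(mask) == length(labels))
  if (!is.null(date)) date <- as.Date(date)
  structure(list(graph = graph, labels = labels, mask = mask, date = date),
            class = "labeled_example")
}

# stack a set of examples into a packed batch with label/mask matrices
examples_batch <- function(examples) {
  labels <- do.call(rbind, lapply(examples, function(e) e$labels))
  mask <- do.call(rbind, lapply(examples, function(e) e$mask))
  labels[!mask] <- NA
  pack_graphs(lapply(examples, function(e) e$graph), labels, mask)
}

#' Pack examples into batches under an atom budget
#'
#' Dynamic batching for variable-size graphs: examples are shuffled with the
#' given seed, sorted by atom count (largest first) and first-fit packed into
#' batches whose total atom count never exceeds `atom_budget`. Every example
#' lands in exactly one batch.
#'
#' @param examples list of [labeled_example()].
#' @param atom_budget maximum total atoms per batch; must be at least the
#'   largest molecule.
#' @param seed shuffle seed.
#' @return list of `packed_batch` objects.
#' @export
pack_batches <- function(examples, atom_budget, seed = 1L) {
  sizes <- vapply(examples, function(e) e$graph$n_atoms, integer(1))
  if (max(sizes) > atom_budget)
    stop(sprintf("molecule with %d atoms exceeds the atom budget %d",
                 max(sizes), atom_budget))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  ord <- sample.int(length(examples))
  ord <- ord[order(-sizes[ord])]           # stable: shuffle breaks ties
  bins <- list(); loads <- integer()
  assign_to <- integer(length(examples))
  for (i in ord) {
    fit <- which(loads + sizes[i] <= atom_budget)
    if (length(fit)) {
      k <- fit[1L]
    } else {
      k <- length(bins) + 1L
      bins[[k]] <- integer(); loads[k] <- 0L
    }
    bins[[k]] <- c(bins[[k]], i)
    loads[k] <- loads[k] + sizes[i]
  }
  lapply(bins, function(ix) examples_batch(examples[ix]))
}

#' Masked multi-task loss
#'
#' Sum over tasks of `weight_t * MSE_t`, where each task's mean squared error
#' is computed only over examples whose label is present; tasks with no
#' present label contribute zero.
#'
#' @param pred,labels numeric matrices (n x n_tasks).
#' @param mask logical presence matrix (defaults to `!is.na(labels)`).
#' @param weights per-task weights (default all 1).
#' @return scalar loss with attribute `"per_task"` (the unweighted MSEs).
#' @export
mt_loss <- function(pred, labels, mask = NULL, weights = NULL) {
  pred <- as.matrix(pred); labels <- as.matrix(labels)
  stopifnot(all(dim(pred) == dim(labels)))
  if (is.null(mask)) mask <- !is.na(labels)
  if (is.null(weights)) weights <- rep(1, ncol(pred))
  per <- numeric(ncol(pred))
  for (t in seq_len(ncol(pred))) {
    m <- mask[, t]
    per[t] <- if (any(m)) mean((pred[m, t] - labels[m, t])^2) else 0
  }
  if (!any(mask)) warning("all labels masked; loss is 0")
  structure(sum(weights * per), per_task = per)
}

# gradient of mt_loss w.r.t. pred
.mt_loss_grad <- function(pred, labels, mask, weights) {
  d <- matrix(0, nrow(pred), ncol(pred))
  for (t in seq_len(ncol(pred))) {
    m <- mask[, t]
    n <- sum(m)
    if (n) d[m, t] <- 2 * weights[t] * (pred[m, t] - labels[m, t]) / n
  }
  d
}

#' Hold out the newest examples for validation
#'
#' Splits labeled examples into a fit set and a validation set by
#' registration date: the newest `fraction` of examples validate, mirroring
#' the chronological train/test protocol. Ties (or absent dates) fall back to
#' stable input order, so the last examples by position are held out.
#'
#' @param examples list of [labeled_example()].
#' @param fraction fraction held out, in (0, 1).
#' @return list with `fit` and `validation`.
#' @export
chronological_validation_split <- function(examples, fraction) {
  stopifnot(fraction > 0, fraction < 1)
  n <- length(examples)
  dates <- vapply(examples, function(e)
    if (is.null(e$date)) NA_real_ else as.numeric(e$date), numeric(1))
  ord <- if (all(is.na(dates))) seq_len(n) else order(dates, seq_len(n))
  n_val <- max(1L, round(n * fraction))
  val_ix <- ord[(n - n_val + 1L):n]
  list(fit = examples[setdiff(ord, val_ix)], validation = examples[val_ix])
}

#' Optimization settings
#'
#' @param learning_rate Adam step size.
#' @param epochs maximum epochs.
#' @param atom_budget atoms per packed batch.
#' @param seed master seed for shuffling (weights are seeded by the network
#'   config).
#' @param val_fraction newest fraction of examples held out for validation
#'   and early stopping; 0 disables validation.
#' @param beta1,beta2,eps Adam moment decay rates and stabilizer.
#' @param patience early-stopping patience in epochs (Inf disables).
#' @param bn_freeze fraction of the epoch budget after which batch-norm
#'   statistics freeze: later epochs train against the fixed running
#'   statistics (the same normalization inference uses), so precise readouts
#'   -- in particular small-task heads under masking -- are optimized
#'   against the features they will be evaluated with. 1 never freezes.
#' @param weights per-task loss weights.
#' @param checkpoint_dir if set, an eval-mode checkpoint is written there
#'   every epoch.
#' @param verbose print per-epoch progress.
#' @return list of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-3, epochs = 100L,
                         atom_budget = 2000L, seed = 1L, val_fraction = 0.1,
                         beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                         patience = 20L, bn_freeze = 0.5, weights = NULL,
                         checkpoint_dir = NULL, verbose = FALSE) {
  stopifnot(learning_rate > 0, epochs >= 1L, atom_budget >= 1L,
            val_fraction >= 0, val_fraction < 1,
            bn_freeze > 0, bn_freeze <= 1)
  structure(list(learning_rate = learning_rate, epochs = as.integer(epochs),
                 atom_budget = as.integer(atom_budget),
                 seed = as.integer(seed), val_fraction = val_fraction,
                 beta1 = beta1, beta2 = beta2, eps = eps,
                 patience = patience, bn_freeze = bn_freeze,
                 weights = weights,
                 checkpoint_dir = checkpoint_dir, verbose = verbose),
            class = "train_config")
}

# union over tasks of the newest `fraction` of each task's labeled examples
.per_task_val_indices <- function(examples, fraction, n_tasks) {
  n <- length(examples)
  dates <- vapply(examples, function(e)
    if (is.null(e$date)) NA_real_ else as.numeric(e$date), numeric(1))
  ord <- if (all(is.na(dates))) seq_len(n) else order(dates, seq_len(n))
  val_ix <- integer()
  for (t in seq_len(n_tasks)) {
    labeled <- ord[vapply(examples[ord], function(e)
      isTRUE(e$mask[t]), logical(1))]
    if (!length(labeled)) next
    n_val <- max(1L, round(length(labeled) * fraction))
    val_ix <- union(val_ix, labeled[(length(labeled) - n_val + 1L):
                                    length(labeled)])
  }
  sort(val_ix)
}

.adam_init <- function(params) {
  list(m = lapply(params, function(x) x * 0),
       v = lapply(params, function(x) x * 0), t = 0L)
}

.adam_step <- function(params, grads, state, cfg) {
  state$t <- state$t + 1L
  bc1 <- 1 - cfg$beta1^state$t
  bc2 <- 1 - cfg$beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- cfg$beta1 * state$m[[nm]] + (1 - cfg$beta1) * g
    state$v[[nm]] <- cfg$beta2 * state$v[[nm]] + (1 - cfg$beta2) * g^2
    params[[nm]] <- params[[nm]] - cfg$learning_rate *
      (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + cfg$eps)
  }
  list(params = params, state = state)
}

#' Train a graph convolutional network
#'
#' Minimizes the masked multi-task MSE with Adam over dynamically packed
#' batches. A chronological validation set is held out for early stopping:
#' with one task, the newest `val_fraction` of examples; with several tasks,
#' the newest `val_fraction` of *each task's labeled examples* (their
#' union), so the validation loss covers every endpoint even when one task
#' is labeled on a small, old subset. Training stops early when the
#' validation loss has not improved for `patience` epochs (never before the
#' batch-norm freeze point), and the parameters of the best validation epoch
#' are returned. Fully deterministic for a given seed.
#'
#' @param examples list of [labeled_example()] (>= 2).
#' @param net a [network_config()] or an already-initialized `gcn_model`
#'   (warm start).
#' @param config a [train_config()].
#' @return list of class `gcn_fit`: `model` (best epoch), `history`
#'   (data.frame with per-epoch train/validation loss and per-task validation
#'   R^2), `best_epoch`.
#' @export
train_gcn <- function(examples, net, config = train_config()) {
  stopifnot(length(examples) >= 2L)
  model <- if (inherits(net, "gcn_model")) net else gcn_init(net)
  n_tasks <- model$config$n_tasks
  weights <- config$weights %||% rep(1, n_tasks)
  if (config$val_fraction > 0) {
    if (n_tasks > 1L) {
      val_ix <- .per_task_val_indices(examples, config$val_fraction, n_tasks)
      fit_set <- examples[setdiff(seq_along(examples), val_ix)]
      val_set <- examples[val_ix]
    } else {
      sp <- chronological_validation_split(examples, config$val_fraction)
      fit_set <- sp$fit; val_set <- sp$validation
    }
  } else {
    fit_set <- examples; val_set <- list()
  }
  val_batch <- if (length(val_set)) examples_batch(val_set) else NULL
  opt <- .adam_init(model$params)
  hist <- list()
  best <- list(loss = Inf, model = model, epoch = 0L)
  stall <- 0L
  freeze_after <- ceiling(config$bn_freeze * config$epochs)
  for (epoch in seq_len(config$epochs)) {
    batches <- pack_batches(fit_set, config$atom_budget,
                            seed = config$seed + epoch)
    # after the freeze point, train against the running (inference-time)
    # batch-norm statistics; only the statistics updates are disabled
    bn_mode <- if (epoch <= freeze_after) "train" else "eval"
    epoch_loss <- 0; epoch_n <- 0L
    for (b in batches) {
      fwd <- gcn_forward(model, b, mode = bn_mode, keep_cache = TRUE)
      model <- fwd$model
      loss <- mt_loss(fwd$pred, b$labels, b$mask, weights)
      if (!is.finite(loss))
        stop(sprintf("training diverged (loss %g) at epoch %d", loss, epoch))
      dPred <- .mt_loss_grad(fwd$pred, b$labels, b$mask, weights)
      grads <- gcn_backward(model, fwd$cache, dPred)
      step <- .adam_step(model$params, grads, opt, config)
      model$params <- step$params
      opt <- step$state
      epoch_loss <- epoch_loss + as.numeric(loss) * b$n_mol
      epoch_n <- epoch_n + b$n_mol
    }
    train_loss <- epoch_loss / epoch_n
    row <- data.frame(epoch = epoch, train_loss = train_loss,
                      val_loss = NA_real_)
    if (!is.null(val_batch)) {
      vf <- gcn_forward(model, val_batch, mode = "eval")
      vloss <- mt_loss(vf$pred, val_batch$labels, val_batch$mask, weights)
      row$val_loss <- as.numeric(vloss)
      if (!is.finite(row$val_loss))
        stop(sprintf("training diverged (validation loss %g) at epoch %d",
                     row$val_loss, epoch))
      for (t in seq_len(n_tasks)) {
        m <- val_batch$mask[, t]
        r2 <- if (sum(m) >= 3L && stats::sd(val_batch$labels[m, t]) > 0)
          r_squared(vf$pred[m, t], val_batch$labels[m, t]) else NA_real_
        row[[paste0("val_r2_", model$config$task_names[t])]] <- r2
      }
      if (row$val_loss < best$loss) {
        best <- list(loss = row$val_loss, model = model, epoch = epoch)
        stall <- 0L
      } else stall <- stall + 1L
    } else {
      best <- list(loss = train_loss, model = model, epoch = epoch)
    }
    hist[[epoch]] <- row
    if (config$verbose)
      message(sprintf("epoch %3d  train %.5f  val %s", epoch, train_loss,
                      format(row$val_loss)))
    if (!is.null(config$checkpoint_dir)) {
      dir.create(config$checkpoint_dir, showWarnings = FALSE, recursive = TRUE)
      save_checkpoint(model, file.path(config$checkpoint_dir,
                                       sprintf("epoch_%04d.json", epoch)))
    }
    # the freeze transition changes the optimization regime: grant the
    # post-freeze phase a fresh patience budget before stopping
    if (epoch == freeze_after) stall <- 0L
    if (!is.null(val_batch) && epoch > freeze_after &&
        stall >= config$patience) break
  }
  history <- do.call(rbind, hist)
  structure(list(model = best$model, history = history,
                 best_epoch = best$epoch), class = "gcn_fit")
}

#' @export
print.gcn_fit <- function(x, ...) {
  cat(sprintf("<gcn_fit: %d epochs run, best epoch %d (val loss %s)>\n",
              nrow(x$history), x$best_epoch,
              format(x$history$val_loss[x$best_epoch])))
  invisible(x)
}
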