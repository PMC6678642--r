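# Single-file JSON checkpoints. Numeric payloads are serialized as "%.17g"
# strings so a save/load round trip reproduces eval-mode outputs bit for bit
# (plain JSON number formatting is not an exact double round trip).

.num_out <- function(x) {
  list(dim = dim(x) %||% NULL, data = sprintf("%.17g", as.numeric(x)))
}

.num_in <- function(obj) {
  v <- as.numeric(obj$data)
  if (!is.null(obj$dim) && length(obj$dim))
    array(v, dim = as.integer(unlist(obj$dim))) else v
}

#' Save a model checkpoint
#'
#' Writes a `gcn_model` or `ensemble_model` (with every base model inlined)
#' to a single JSON file: configuration, parameters and batch-norm running
#' statistics, at full double precision.
#'
#' @param model a `gcn_model` or `ensemble_model`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(model, path) {
  obj <- if (inherits(model, "gcn_model")) .gcn_to_list(model)
         else if (inherits(model, "ensemble_model")) .ens_to_list(model)
         else stop("unsupported model class")
  jsonlite::write_json(obj, path, auto_unbox = TRUE, null = "null",
                       digits = NA)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path a file written by [save_checkpoint()].
#' @return the restored model.
#' @export
load_checkpoint <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE,
                             simplifyMatrix = FALSE)
  switch(obj$kind,
         gcn = .gcn_from_list(obj),
         ensemble = .ens_from_list(obj),
         stop("unrecognized checkpoint kind: ", obj$kind))
}

.gcn_to_list <- function(model) {
  cfg <- model$config
  list(kind = "gcn",
       config = list(n_conv_layers = cfg$n_conv_layers,
                     transform_widths = as.list(cfg$transform_widths),
                     head_widths = as.list(cfg$head_widths),
                     n_tasks = cfg$n_tasks, alpha = cfg$alpha,
                     bn_momentum = cfg$bn_momentum, bn_eps = cfg$bn_eps,
                     seed = cfg$seed, task_names = as.list(cfg$task_names),
                     graph = list(distance_cutoff = cfg$graph$distance_cutoff,
                                  max_neighbors = cfg$graph$max_neighbors,
                                  vocab = as.list(cfg$graph$vocab))),
       params = lapply(model$params, .num_out),
       bn = lapply(model$bn, function(s)
         list(mean = .num_out(s$mean), var = .num_out(s$var))))
}

.gcn_from_list <- function(obj) {
  c0 <- obj$config
  cfg <- network_config(
    n_conv_layers = as.integer(c0$n_conv_layers),
    transform_widths = as.integer(unlist(c0$transform_widths)),
    head_widths = as.integer(unlist(c0$head_widths)),
    n_tasks = as.integer(c0$n_tasks), alpha = c0$alpha,
    bn_momentum = c0$bn_momentum, bn_eps = c0$bn_eps,
    seed = as.integer(c0$seed),
    task_names = as.character(unlist(c0$task_names)),
    graph = graph_config(c0$graph$distance_cutoff,
                         as.integer(c0$graph$max_neighbors),
                         as.character(unlist(c0$graph$vocab))))
  params <- lapply(obj$params, .num_in)
  bn <- lapply(obj$bn, function(s)
    list(mean = .num_in(s$mean), var = .num_in(s$var)))
  structure(list(config = cfg, params = params, bn = bn),
            class = "gcn_model")
}

.ens_to_list <- function(ens) {
  list(kind = "ensemble",
       enc_width = ens$enc_width, explicit_width = ens$explicit_width,
       n_tasks = ens$n_tasks, alpha = ens$alpha,
       task_names = as.list(ens$task_names),
       members = lapply(ens$members, .gcn_to_list),
       enc = lapply(ens$enc, function(e)
         list(W = .num_out(e$W), b = .num_out(e$b))),
       head = lapply(ens$head, function(h)
         list(W = .num_out(h$W), b = .num_out(h$b))))
}

.ens_from_list <- function(obj) {
  structure(list(
    members = lapply(obj$members, .gcn_from_list),
    enc = lapply(obj$enc, function(e)
      list(W = .num_in(e$W), b = .num_in(e$b))),
    head = lapply(obj$head, function(h)
      list(W = .num_in(h$W), b = .num_in(h$b))),
    enc_width = as.integer(obj$enc_width),
    explicit_width = as.integer(obj$explicit_width),
    n_tasks = as.integer(obj$n_tasks), alpha = obj$alpha,
    task_names = as.character(unlist(obj$task_names))),
    class = "ensemble_model")
}
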