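#' Clean raw assay values
#'
#' Applies the warehouse quality rules to a table of assay records:
#' non-numeric values are dropped, leading quantifiers (`<`, `>`, `~`,
#' `>=`, `<=`, unicode approximations) are stripped with the bare number kept
#' and flagged as censored, and duplicated (compound, endpoint) records are
#' replaced by the mean of their values on the raw scale.
#'
#' @param records data.frame with columns `compound_id`, `endpoint`, `value`
#'   (character or numeric) and optionally `smiles`, `date`.
#' @return list with `records` (cleaned data.frame: `compound_id`,
#'   `endpoint`, `value` numeric, `censored` logical, plus carried columns)
#'   and `report` (counts: `input`, `dropped_non_numeric`,
#'   `quantifier_stripped`, `duplicates_averaged`, `retained`).
#' @export
clean_values <- function(records) {
  stopifnot(all(c("compound_id", "endpoint", "value") %in% names(records)))
  if (!nrow(records)) {
    rep0 <- list(input = 0L, dropped_non_numeric = 0L,
                 quantifier_stripped = 0L, duplicates_averaged = 0L,
                 retained = 0L)
    return(list(records = cbind(records, censored = logical()),
                report = rep0))
  }
  raw <- trimws(as.character(records$value))
  quant_re <- "^(<=|>=|<|>|~|≃|≈)\\s*"
  censored <- grepl(quant_re, raw)
  stripped <- sub(quant_re, "", raw)
  num <- suppressWarnings(as.numeric(stripped))
  keep <- !is.na(num)
  dropped <- sum(!keep)
  cleaned <- records[keep, setdiff(names(records), "value"), drop = FALSE]
  cleaned$value <- num[keep]
  cleaned$censored <- censored[keep]
  # average duplicates on the raw scale, keeping first-seen metadata
  key <- paste(cleaned$compound_id, cleaned$endpoint, sep = "\r")
  dup_groups <- sum(table(key) > 1L)
  agg <- !duplicated(key)
  means <- tapply(cleaned$value, key, mean)
  cens <- tapply(cleaned$censored, key, any)
  out <- cleaned[agg, , drop = FALSE]
  out$value <- as.numeric(means[paste(out$compound_id, out$endpoint,
                                      sep = "\r")])
  out$censored <- as.logical(cens[paste(out$compound_id, out$endpoint,
                                        sep = "\r")])
  rownames(out) <- NULL
  list(records = out,
       report = list(input = nrow(records),
                     dropped_non_numeric = dropped,
                     quantifier_stripped = sum(censored[keep]),
                     duplicates_averaged = dup_groups,
                     retained = nrow(records) - dropped))
}

#' Transform assay values for modeling
#'
#' `log10` for positive-valued endpoints (clearance, IC50, solubility);
#' `logit` for bounded percent-of-control endpoints, scaling by `scale`
#' (100 for percentages), clamping to `[eps, 1 - eps]` and taking
#' `log(p / (1 - p))`; `none` passes through. [inverse_transform_values()]
#' inverts exactly on the valid domain.
#'
#' @param values numeric vector.
#' @param mode `"none"`, `"log10"` or `"logit"`.
#' @param eps logit clamp.
#' @param scale logit input scale (values are divided by it).
#' @return transformed numeric vector; under `log10`, nonpositive inputs
#'   yield `NA` with a warning naming the offending count.
#' @export
transform_values <- function(values, mode = c("none", "log10", "logit"),
                             eps = 1e-3, scale = 100) {
  mode <- match.arg(mode)
  switch(mode,
    none = values,
    log10 = {
      bad <- !is.na(values) & values <= 0
      if (any(bad))
        warning(sprintf("%d nonpositive value(s) cannot be log10-transformed",
                        sum(bad)))
      out <- values
      out[bad] <- NA_real_
      out[!bad] <- log10(out[!bad])
      out
    },
    logit = {
      p <- pmin(pmax(values / scale, eps), 1 - eps)
      log(p / (1 - p))
    })
}

#' @rdname transform_values
#' @param transformed values on the transformed scale.
#' @export
inverse_transform_values <- function(transformed,
                                     mode = c("none", "log10", "logit"),
                                     eps = 1e-3, scale = 100) {
  mode <- match.arg(mode)
  switch(mode,
    none = transformed,
    log10 = 10^transformed,
    logit = scale * stats::plogis(transformed))
}

#' Records present only in a newer table
#'
#' Keyed by (compound, endpoint): returns the new-table records whose key is
#' absent from the old table or whose value changed, i.e. everything an
#' incremental model refresh must train on.
#'
#' @param old,new data.frames with `compound_id`, `endpoint`, `value`.
#' @return subset of `new`.
#' @export
incremental_diff <- function(old, new) {
  key <- function(d) paste(d$compound_id, d$endpoint, sep = "\r")
  old_val <- structure(old$value, names = key(old))
  k <- key(new)
  fresh <- !(k %in% names(old_val)) |
    !vapply(seq_len(nrow(new)), function(i)
      isTRUE(all.equal(unname(old_val[k[i]]), new$value[i])), logical(1))
  out <- new[fresh, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# ---- SDF I/O --------------------------------------------------------------

#' Write molecules to an SDF (V2000) file
#'
#' Fixed-width MDL V2000 with coordinates, bond orders, `M CHG` lines for
#' nonzero formal charges, and `id` / optional `date` data fields.
#'
#' @param mols list of [molecule()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_sdf <- function(mols, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (mol in mols) {
    n <- n_atoms(mol); m <- nrow(mol$bonds)
    lines <- c(mol$id, "  molgcn", "",
               sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, m))
    for (a in seq_len(n))
      lines <- c(lines, sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                                mol$coords[a, 1], mol$coords[a, 2],
                                mol$coords[a, 3], mol$elements[a]))
    if (m)
      lines <- c(lines, sprintf("%3d%3d%3d  0  0  0  0", mol$bonds$i,
                                mol$bonds$j, mol$bonds$order))
    chg <- which(mol$charges != 0L)
    if (length(chg))
      lines <- c(lines, paste0("M  CHG", sprintf("%3d", length(chg)),
                               paste0(sprintf("%4d%4d", chg,
                                              mol$charges[chg]),
                                      collapse = "")))
    lines <- c(lines, "M  END", "> <id>", mol$id, "")
    if (!is.null(mol$date))
      lines <- c(lines, "> <date>", format(mol$date), "")
    lines <- c(lines, "$$$$")
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read molecules from an SDF (V2000) file
#'
#' Parses via ChemmineR and recovers the formal charges from `M CHG` lines
#' (which ChemmineR's container does not carry). Coordinates are honored
#' as given.
#'
#' @param path SDF file.
#' @return list of [molecule()].
#' @export
read_sdf <- function(path) {
  sdfs <- ChemmineR::read.SDFset(path)
  raw <- readLines(path)
  # split raw text per record for the charge lines and data fields
  ends <- which(trimws(raw) == "$$$$")
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  lapply(seq_along(ChemmineR::cid(sdfs)), function(i) {
    sdf <- sdfs[[i]]
    ab <- ChemmineR::atomblock(sdf)
    bb <- ChemmineR::bondblock(sdf)
    elements <- sub("_.*$", "", rownames(ab))
    coords <- unname(ab[, 1:3, drop = FALSE])
    bonds <- if (is.null(dim(bb)) || nrow(bb) == 0L) empty_bonds() else
      data.frame(i = as.integer(bb[, 1L]), j = as.integer(bb[, 2L]),
                 order = as.integer(bb[, 3L]))
    rec <- raw[starts[i]:ends[i]]
    charges <- integer(length(elements))
    for (ln in grep("^M  CHG", rec, value = TRUE)) {
      flds <- as.integer(strsplit(trimws(sub("^M  CHG\\s*\\d+", "", ln)),
                                  "\\s+")[[1L]])
      if (length(flds) >= 2L) {
        ix <- flds[seq(1L, length(flds), by = 2L)]
        ch <- flds[seq(2L, length(flds), by = 2L)]
        charges[ix] <- ch
      }
    }
    db <- ChemmineR::datablock(sdf)
    id <- if ("id" %in% names(db)) unname(db[["id"]]) else
      ChemmineR::sdfid(sdf)
    date <- if ("date" %in% names(db)) as.Date(unname(db[["date"]])) else NULL
    molecule(id, elements, coords, bonds, charges, date = date)
  })
}

# ---- conformer provider ---------------------------------------------------

#' Conformer provider backed by OpenBabel
#'
#' Returns a function that turns a SMILES string (plus id) into a
#' [molecule()] with generated 3D coordinates, via ChemmineOB when available
#' or the `obabel` command-line tool. Coordinate generation in OpenBabel is
#' deterministic for a given input.
#'
#' @return function(smiles, id, date = NULL) -> [molecule()] or `NULL` on
#'   parse failure.
#' @export
openbabel_conformer_provider <- function() {
  function(smiles, id, date = NULL) {
    sdf_text <- NULL
    if (requireNamespace("ChemmineOB", quietly = TRUE)) {
      sdf_text <- tryCatch(
        ChemmineOB::convertFormat("SMI", "SDF",
                                  source = paste(smiles, id),
                                  options = data.frame(names = "gen3d",
                                                       args = "")),
        error = function(e) NULL)
    }
    if (is.null(sdf_text) && nzchar(Sys.which("obabel"))) {
      out <- tempfile(fileext = ".sdf")
      status <- suppressWarnings(system2(
        "obabel", c(paste0("-:", shQuote(paste(smiles, id))), "-osdf",
                    "--gen3d", "-O", out),
        stdout = FALSE, stderr = FALSE))
      if (status == 0L && file.exists(out))
        sdf_text <- paste(readLines(out), collapse = "\n")
    }
    if (is.null(sdf_text) || !nzchar(sdf_text)) return(NULL)
    tmp <- tempfile(fileext = ".sdf")
    writeLines(sdf_text, tmp)
    on.exit(unlink(tmp))
    mols <- tryCatch(read_sdf(tmp), error = function(e) NULL)
    if (is.null(mols) || !length(mols)) return(NULL)
    mol <- mols[[1L]]
    mol$id <- id
    mol$smiles <- smiles
    mol$date <- if (is.null(date)) NULL else as.Date(date)
    mol
  }
}

#' Read a labeled dataset from CSV (and optional SDF)
#'
#' Ingests a comma-delimited assay table with columns `id`, one column per
#' endpoint, and optionally `smiles` and `date`. Structures come from the
#' SDF when given (matched by id, coordinates honored); otherwise each
#' SMILES is passed to the conformer provider. Values are cleaned with
#' [clean_values()], transformed per task, and missing endpoints are masked.
#'
#' @param csv_path assay CSV (UTF-8, header row required).
#' @param tasks list of [task_spec()]; endpoint names must match columns.
#' @param sdf_path optional SDF with structures.
#' @param conformer_provider function(smiles, id, date) used when no SDF
#'   structure exists; defaults to [openbabel_conformer_provider()].
#' @param config a [graph_config()].
#' @return list with `examples` (list of [labeled_example()]), `skipped`
#'   (ids without a structure), `clean_report` (per-endpoint cleaning
#'   counts).
#' @export
read_dataset <- function(csv_path, tasks, sdf_path = NULL,
                         conformer_provider = openbabel_conformer_provider(),
                         config = graph_config()) {
  tab <- utils::read.csv(csv_path, stringsAsFactors = FALSE,
                         check.names = FALSE)
  stopifnot("id" %in% names(tab))
  task_names <- vapply(tasks, function(t) t$name, character(1))
  missing_cols <- setdiff(task_names, names(tab))
  if (length(missing_cols))
    stop("endpoint column(s) missing from CSV: ",
         paste(missing_cols, collapse = ", "))
  # long format -> clean per endpoint
  long <- do.call(rbind, lapply(task_names, function(tn)
    data.frame(compound_id = tab$id, endpoint = tn,
               value = as.character(tab[[tn]]),
               stringsAsFactors = FALSE)))
  cleaned <- clean_values(long)
  label_of <- new.env(parent = emptyenv())
  for (r in seq_len(nrow(cleaned$records))) {
    rec <- cleaned$records[r, ]
    t <- tasks[[match(rec$endpoint, task_names)]]
    assign(paste(rec$compound_id, rec$endpoint, sep = "\r"),
           transform_values(rec$value, t$transform), envir = label_of)
  }
  sdf_mols <- if (!is.null(sdf_path)) read_sdf(sdf_path) else list()
  sdf_ids <- vapply(sdf_mols, function(m) m$id, character(1))
  examples <- list()
  skipped <- character()
  for (r in seq_len(nrow(tab))) {
    id <- as.character(tab$id[r])
    date <- if ("date" %in% names(tab)) tab$date[r] else NULL
    mol <- if (id %in% sdf_ids) sdf_mols[[match(id, sdf_ids)]] else NULL
    if (is.null(mol) && "smiles" %in% names(tab))
      mol <- conformer_provider(tab$smiles[r], id, date)
    if (is.null(mol)) {
      skipped <- c(skipped, id)
      next
    }
    if (!is.null(date) && is.null(mol$date)) mol$date <- as.Date(date)
    labels <- vapply(task_names, function(tn) {
      v <- mget(paste(id, tn, sep = "\r"), envir = label_of,
                ifnotfound = list(NA_real_))[[1L]]
      as.numeric(v)
    }, numeric(1))
    examples[[length(examples) + 1L]] <-
      labeled_example(build_graph(mol, config), labels, date = mol$date)
  }
  if (length(skipped))
    message(sprintf("skipped %d record(s) without a parsable structure",
                    length(skipped)))
  list(examples = examples, skipped = skipped,
       clean_report = cleaned$report)
}

#' Write a labeled dataset to CSV (+ SDF)
#'
#' Inverse of [read_dataset()] for fixture shipping: writes the id/date and
#' per-endpoint label columns to CSV and the structures to SDF.
#'
#' @param mols list of [molecule()].
#' @param labels numeric matrix (one row per molecule, named columns).
#' @param csv_path,sdf_path output files (either may be `NULL`).
#' @return invisibly, a list of the written paths.
#' @export
write_dataset <- function(mols, labels, csv_path, sdf_path = NULL) {
  labels <- as.matrix(labels)
  stopifnot(nrow(labels) == length(mols))
  tab <- data.frame(id = vapply(mols, function(m) m$id, character(1)))
  dates <- vapply(mols, function(m)
    if (is.null(m$date)) NA_character_ else format(m$date), character(1))
  if (!all(is.na(dates))) tab$date <- dates
  for (j in seq_len(ncol(labels))) tab[[colnames(labels)[j]]] <- labels[, j]
  if (!is.null(csv_path))
    utils::write.csv(tab, csv_path, row.names = FALSE, quote = FALSE)
  if (!is.null(sdf_path)) write_sdf(mols, sdf_path)
  invisible(list(csv = csv_path, sdf = sdf_path))
}
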