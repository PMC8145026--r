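#' Read a numeric data matrix from delimited text
#'
#' Reads an n x d matrix from a plain-text file. The delimiter is
#' auto-detected among comma, tab and whitespace from the first data line; a
#' single leading header line is skipped automatically when its fields are
#' not all numeric (the point-file dialect of the common clustering
#' benchmark suites).
#'
#' @param path file path.
#' @param quiet suppress the row/column count message.
#' @return numeric matrix.
#' @export
read_matrix <- function(path, quiet = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  idx <- which(keep)
  if (!length(idx)) stop("no data lines in ", path)
  first <- lines[idx[1]]
  sep <- if (grepl(",", first, fixed = TRUE)) ","
         else if (grepl("\t", first, fixed = TRUE)) "\t"
         else "[ ]+"
  toks <- lapply(lines[idx], function(l) {
    t <- strsplit(trimws(l), sep)[[1]]
    trimws(t[nzchar(t)])
  })
  vals1 <- suppressWarnings(as.numeric(toks[[1]]))
  header <- anyNA(vals1)
  if (header) {
    if (length(toks) < 2) stop("only a header line found in ", path)
    toks <- toks[-1]
    idx <- idx[-1]
  }
  d <- length(toks[[1]])
  lens <- lengths(toks)
  if (any(lens != d))
    stop("ragged row at line ", idx[which(lens != d)[1]], " of ", path,
         " (expected ", d, " fields, found ", lens[lens != d][1], ")")
  vals <- suppressWarnings(lapply(toks, as.numeric))
  bad <- which(vapply(vals, anyNA, TRUE))
  if (length(bad)) {
    col <- which(is.na(vals[[bad[1]]]))[1]
    stop("non-numeric value at line ", idx[bad[1]], ", field ", col,
         " of ", path)
  }
  X <- do.call(rbind, vals)
  if (!quiet) message("read ", nrow(X), " x ", ncol(X), " matrix from ", path)
  X
}

#' Read integer cluster labels (one per line)
#'
#' Labels need not be contiguous; they are remapped to 1..L in increasing
#' order of the original values, and the mapping is reported.
#'
#' @param path file path.
#' @param quiet suppress the remapping message.
#' @return integer vector of labels in 1..L, with the original values in
#'   attribute `"levels"`.
#' @export
read_labels <- function(path, quiet = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  raw <- suppressWarnings(as.integer(lines))
  if (anyNA(raw))
    stop("non-integer label at data line ", which(is.na(raw))[1], " of ", path)
  lev <- sort(unique(raw))
  out <- match(raw, lev)
  attr(out, "levels") <- lev
  if (!quiet && !identical(lev, seq_along(lev)))
    message("remapped labels {", paste(lev, collapse = ", "), "} to 1..",
            length(lev))
  out
}

#' Write a clustering fit to disk
#'
#' Emits `labels.txt` (one integer per line) and `result.json` holding the
#' estimated parameters, hyperparameters, seed, iteration count, convergence
#' flag and the full energy trace. Numbers are serialized with 17
#' significant digits so that re-reading reproduces the estimates
#' bit-for-bit.
#'
#' @param result a `"pareto_fit"` from [pareto_cluster()].
#' @param outdir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
write_result <- function(result, outdir) {
  if (!inherits(result, "pareto_fit")) stop("'result' must be a pareto_fit")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  lab_path <- file.path(outdir, "labels.txt")
  json_path <- file.path(outdir, "result.json")
  writeLines(as.character(result$labels), lab_path)
  doc <- list(
    centers = result$params$centers,
    covariances = result$params$covariances,
    proportions = result$params$proportions,
    hyperparams = list(mode = result$mode, tau = result$tau,
                       beta = result$beta, estimate_cov = result$estimate_cov,
                       estimate_pi = result$estimate_pi,
                       ridge_alpha = result$ridge_alpha),
    seed = result$seed,
    n_iter = result$n_iter,
    converged = result$converged,
    energy_trace = result$energy_trace)
  jsonlite::write_json(doc, json_path, digits = I(17), auto_unbox = TRUE,
                       null = "null", always_decimal = TRUE)
  invisible(c(labels = lab_path, result = json_path))
}

#' Write sampled data with a scenario sidecar
#'
#' Emits `samples.tsv` (tab-delimited, no header) and `scenario.json`
#' recording the generating parameters and seed.
#'
#' @param X n x d matrix of draws (e.g. from [mh_sample()]).
#' @param scenario the [simulation_scenario()] that generated them.
#' @param outdir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
write_samples <- function(X, scenario, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  data_path <- file.path(outdir, "samples.tsv")
  json_path <- file.path(outdir, "scenario.json")
  utils::write.table(X, data_path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  doc <- list(
    centers = scenario$theta_star$centers,
    covariances = scenario$theta_star$covariances,
    proportions = scenario$theta_star$proportions,
    tau = scenario$tau, beta = scenario$beta,
    n = scenario$n, reps = scenario$reps, seed = scenario$seed,
    acceptance_rate = attr(X, "acceptance_rate"))
  jsonlite::write_json(doc, json_path, digits = I(17), auto_unbox = TRUE,
                       null = "null")
  invisible(c(samples = data_path, scenario = json_path))
}

#' Read back a result.json written by [write_result()]
#'
#' @param path path to a `result.json`.
#' @return list with `centers`, `covariances` (list of matrices),
#'   `proportions`, `hyperparams`, `seed`, `n_iter`, `converged`,
#'   `energy_trace`.
#' @export
read_result <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  doc$centers <- as.matrix(doc$centers)
  covs <- doc$covariances
  if (is.array(covs) && length(dim(covs)) == 3) {
    covs <- lapply(seq_len(dim(covs)[1]), function(k) covs[k, , ])
  } else {
    covs <- lapply(covs, as.matrix)
  }
  doc$covariances <- covs
  doc
}
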