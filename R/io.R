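# Serialization: delimited text for time series and matrices (full-precision,
# inspectable, lossless round-trip), JSON for model parameters and configs.

#' Write / read a delimited time-series table
#'
#' Tab-separated text with a header row; numeric columns are written at full
#' double precision so the round trip is lossless.
#'
#' @param path File path.
#' @param payload Data frame of numeric columns.
#' @return `read_series` returns the data frame; `write_series` the path,
#'   invisibly.
#' @export
write_series <- function(path, payload) {
  payload <- as.data.frame(payload)
  cols <- lapply(payload, function(col)
    if (is.numeric(col)) sprintf("%.17g", col) else as.character(col))
  lines <- c(paste(names(payload), collapse = "\t"),
             do.call(paste, c(cols, sep = "\t")))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_series
#' @export
read_series <- function(path) {
  if (!file.exists(path)) stop_dyntrf("no such file: %s", path)
  lines <- readLines(path)
  if (!length(lines)) stop_dyntrf("%s: empty file", path)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  ncol <- length(header)
  rows <- strsplit(lines[-1], "\t", fixed = TRUE)
  for (i in seq_along(rows)) {
    if (length(rows[[i]]) != ncol)
      stop_dyntrf("%s: ragged row at line %d (%d fields, expected %d)",
                  path, i + 1L, length(rows[[i]]), ncol)
  }
  out <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(out) <- header
  for (j in seq_len(ncol)) {
    v <- suppressWarnings(as.numeric(out[[j]]))
    bad <- which(is.na(v) & !is.na(out[[j]]) & out[[j]] != "NA")
    if (length(bad))
      stop_dyntrf("%s: non-numeric value in column '%s' at line %d",
                  path, header[j], bad[1] + 1L)
    if (anyNA(v))
      stop_dyntrf("%s: missing value in column '%s' at line %d",
                  path, header[j], which(is.na(v))[1] + 1L)
    out[[j]] <- v
  }
  out
}

#' Write / read a matrix with axis metadata
#'
#' Full-precision tab-separated values preceded by a commented JSON metadata
#' header (`#meta ...`) carrying the axis names and any extra fields.
#'
#' @param path File path.
#' @param mat Numeric matrix.
#' @param meta Named list of metadata (serialized as JSON).
#' @return `read_matrix` returns the matrix with the metadata in attribute
#'   `meta`; `write_matrix` the path, invisibly.
#' @export
write_matrix <- function(path, mat, meta = list()) {
  mat <- as.matrix(mat)
  meta$nrow <- nrow(mat); meta$ncol <- ncol(mat)
  hdr <- paste0("#meta ", jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA))
  body <- apply(mat, 1, function(r) paste(sprintf("%.17g", r), collapse = "\t"))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  if (!file.exists(path)) stop_dyntrf("no such file: %s", path)
  lines <- readLines(path)
  if (!startsWith(lines[1], "#meta "))
    stop_dyntrf("%s: missing metadata header", path)
  meta <- jsonlite::fromJSON(sub("^#meta ", "", lines[1]))
  rows <- strsplit(lines[-1], "\t", fixed = TRUE)
  for (i in seq_along(rows))
    if (length(rows[[i]]) != meta$ncol)
      stop_dyntrf("%s: ragged row at line %d", path, i + 1L)
  mat <- do.call(rbind, lapply(rows, as.numeric))
  if (anyNA(mat)) stop_dyntrf("%s: non-numeric entries", path)
  attr(mat, "meta") <- meta
  mat
}

#' Write / read fitted model parameters as JSON
#'
#' Serializes a [gm_noise_model()] with the accompanying observation-noise
#' variance, transition coefficient, and a provenance block (seed, backend,
#' package version) under a schema version.
#'
#' @param path File path.
#' @param model A [gm_noise_model()].
#' @param sigma2,alpha Scalars.
#' @param provenance Named list (seed, config digest, ...).
#' @return `read_model` returns a list with `model`, `sigma2`, `alpha`,
#'   `provenance`; `write_model` the path, invisibly.
#' @export
write_model <- function(path, model, sigma2, alpha, provenance = list()) {
  payload <- list(
    schema = "dyntrf-model/1",
    M = model$M, W = model$W, diagonal_only = model$diagonal_only,
    probs = model$probs,
    means = lapply(seq_len(model$M), function(m) model$means[, m]),
    covs = lapply(model$covs, function(C) as.numeric(C)),
    d = nrow(model$means),
    sigma2 = sigma2, alpha = alpha,
    provenance = c(provenance,
                   list(package = "dyntrf",
                        version = as.character(utils::packageVersion("dyntrf")))))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  p <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!identical(p$schema, "dyntrf-model/1"))
    stop_dyntrf("%s: unknown model schema", path)
  d <- p$d
  means <- if (is.matrix(p$means)) t(p$means) else
    matrix(unlist(p$means), nrow = d)
  covs <- lapply(seq_len(p$M), function(m) {
    v <- if (is.list(p$covs)) p$covs[[m]] else p$covs[m, ]
    matrix(v, d, d)
  })
  list(model = gm_noise_model(p$probs, means, covs, W = p$W,
                              diagonal_only = isTRUE(p$diagonal_only)),
       sigma2 = p$sigma2, alpha = p$alpha, provenance = p$provenance)
}

# Write a trf_series as two matrix files plus the state matrix.
write_trf <- function(dir, trf, prefix = "trf") {
  meta <- list(lags_s = trf$lags, time_s = trf$time_s, t0 = trf$t0,
               F_s = trf$F_s, estimator = trf$estimator)
  write_matrix(file.path(dir, paste0(prefix, "_spk1.tsv")), trf$tau1, meta)
  write_matrix(file.path(dir, paste0(prefix, "_spk2.tsv")), trf$tau2, meta)
  write_matrix(file.path(dir, paste0(prefix, "_states.tsv")), trf$states, meta)
  invisible(dir)
}
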