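#' Read and write spike-event files
#'
#' Delimited text with a header and columns `trial`, `neuron`, `time_ms`,
#' deterministically ordered by (trial, time, neuron).
#'
#' @param spikes data.frame of spike events
#' @param path file path
#' @return `read_spikes` returns the data.frame
#' @export
write_spikes <- function(spikes, path) {
  s <- spikes[order(spikes$trial, spikes$time_ms, spikes$neuron),
              c("trial", "neuron", "time_ms")]
  write.csv(s, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spikes
#' @export
read_spikes <- function(path) {
  read.csv(path)
}

#' Read and write PSTH tables
#'
#' Delimited text: first column the neuron id, remaining columns the
#' bin-center times (ms) of 20 ms bins. One file per trial type.
#'
#' @param psth time x neurons rate matrix with `attr(, "times")`
#' @param path file path
#' @param neurons neuron ids (defaults to the column index)
#' @return `read_psth` returns the rate matrix with times attached
#' @export
write_psth <- function(psth, path, neurons = seq_len(ncol(psth))) {
  times <- attr(psth, "times")
  df <- data.frame(neuron = neurons, t(unclass(psth)))
  names(df) <- c("neuron", sprintf("t%.0f", times))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_psth
#' @export
read_psth <- function(path) {
  df <- read.csv(path)
  times <- as.numeric(sub("^t", "", names(df)[-1]))
  m <- t(as.matrix(df[, -1, drop = FALSE]))
  dimnames(m) <- NULL
  structure(m, times = times, neurons = df$neuron,
            class = c("ss_psth", "matrix"))
}

#' Weight-snapshot container
#'
#' Portable directory container with named arrays: a `manifest.json`
#' carrying a schema-version attribute and the array index, each matrix
#' stored as (row, col, value) triplets in plain CSV, and plain vectors as
#' single-column CSV.
#'
#' @param arrays named list of matrices (dense or `Matrix` sparse) and
#'   numeric vectors
#' @param path container directory
#' @return `read_weights` returns the named list (matrices sparse)
#' @export
write_weights <- function(arrays, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  idx <- list()
  for (nm in names(arrays)) {
    a <- arrays[[nm]]
    f <- file.path(path, paste0(nm, ".csv"))
    if (is.matrix(a) || methods::is(a, "Matrix")) {
      tr <- methods::as(methods::as(a, "CsparseMatrix"), "TsparseMatrix")
      write.csv(data.frame(row = tr@i + 1L, col = tr@j + 1L, value = tr@x),
                f, row.names = FALSE)
      idx[[nm]] <- list(kind = "matrix", dims = dim(a), file = basename(f))
    } else {
      write.csv(data.frame(value = as.numeric(a)), f, row.names = FALSE)
      idx[[nm]] <- list(kind = "vector", dims = length(a), file = basename(f))
    }
  }
  jsonlite::write_json(list(schema_version = "1.0", arrays = idx),
                       file.path(path, "manifest.json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_weights
#' @export
read_weights <- function(path) {
  man <- jsonlite::read_json(file.path(path, "manifest.json"),
                             simplifyVector = TRUE)
  out <- list()
  for (nm in names(man$arrays)) {
    e <- man$arrays[[nm]]
    df <- read.csv(file.path(path, e$file))
    if (e$kind == "matrix") {
      out[[nm]] <- Matrix::sparseMatrix(i = df$row, j = df$col, x = df$value,
                                        dims = as.integer(unlist(e$dims)))
    } else {
      out[[nm]] <- df$value
    }
  }
  out
}
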