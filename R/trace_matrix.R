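#' Cells-by-timepoints trace container
#'
#' The common currency of simulation, fitting and feature extraction: a
#' numeric matrix of single-cell traces (fluorescence or molecule
#' counts), one row per cell, on a shared time grid that includes at
#' least two pre-stimulus frames for baseline estimation.
#'
#' @param time shared time grid (h), strictly increasing.
#' @param values cells x timepoints numeric matrix.
#' @param stimulus_onsets onset time(s) of the stimulus pulses (h).
#' @param metadata named list (condition label, platform, gene, seeds, ...).
#' @return An object of class \code{trace_matrix}.
#' @export
trace_matrix <- function(values, time, stimulus_onsets = 0,
                         metadata = list()) {
  values <- as.matrix(values)
  if (length(time) != ncol(values))
    stop("length(time) must equal ncol(values)")
  if (is.unsorted(time, strictly = TRUE))
    stop("time must be strictly increasing")
  structure(list(time = as.numeric(time), values = values,
                 stimulus_onsets = as.numeric(stimulus_onsets),
                 metadata = metadata),
            class = "trace_matrix")
}

#' @export
print.trace_matrix <- function(x, ...) {
  cat(sprintf("<trace_matrix> %d cells x %d timepoints, t = [%g, %g] h\n",
              nrow(x$values), ncol(x$values), min(x$time), max(x$time)))
  if (length(x$metadata))
    cat("  metadata:", paste(names(x$metadata), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.trace_matrix <- function(x) dim(x$values)

#' Population mean trace of a trace matrix
#' @param tm a \code{trace_matrix}.
#' @return Numeric vector, one value per timepoint.
#' @export
mean_trace <- function(tm) colMeans(tm$values)
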