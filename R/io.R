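#' Write / read a trace matrix as delimited text
#'
#' Traces travel as a plain CSV (one row per cell, header = times in
#' hours, first column a cell identifier) with a small YAML sidecar
#' (\code{<path>.yml}) carrying the stimulus onsets and metadata.
#'
#' @param tm a [trace_matrix()].
#' @param path CSV file path.
#' @return \code{write_traces} returns \code{path} invisibly.
#' @export
write_traces <- function(tm, path) {
  df <- data.frame(cell = seq_len(nrow(tm$values)), tm$values,
                   check.names = FALSE)
  names(df) <- c("cell", format(tm$time, trim = TRUE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  meta <- tm$metadata
  meta$truth <- NULL  # latent matrices stay in-memory only
  yaml::write_yaml(list(stimulus_onsets = tm$stimulus_onsets,
                        metadata = meta),
                   paste0(path, ".yml"))
  invisible(path)
}

#' @rdname write_traces
#' @param drop_incomplete drop rows containing missing values (the
#'   analysis keeps only traces complete over the full movie); the
#'   number dropped is reported as a message.
#' @return \code{read_traces} returns a validated [trace_matrix()].
#' @export
read_traces <- function(path, drop_incomplete = TRUE) {
  lines <- readLines(path)
  if (!length(lines)) stop("empty trace file: ", path)
  nfield <- lengths(strsplit(lines, ",", fixed = TRUE))
  if (any(nfield != nfield[1]))
    stop("ragged row at line ", which(nfield != nfield[1])[1], " of ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  if (names(df)[1] != "cell")
    stop("malformed header: first column must be 'cell'")
  time <- suppressWarnings(as.numeric(names(df)[-1]))
  if (any(is.na(time)) || is.unsorted(time, strictly = TRUE))
    stop("malformed header: times must be numeric and strictly increasing")
  values <- as.matrix(df[, -1, drop = FALSE])
  if (drop_incomplete) {
    ok <- stats::complete.cases(values)
    if (any(!ok))
      message(sum(!ok), " incomplete trace(s) dropped, ",
              sum(ok), " retained")
    values <- values[ok, , drop = FALSE]
  }
  side <- paste0(path, ".yml")
  onsets <- 0; meta <- list()
  if (file.exists(side)) {
    sc <- yaml::read_yaml(side)
    onsets <- sc$stimulus_onsets
    meta <- if (is.null(sc$metadata)) list() else sc$metadata
  }
  trace_matrix(values, time, stimulus_onsets = onsets, metadata = meta)
}

#' Run the simulate-and-analyze pipeline
#'
#' One-call pipeline: generate a synthetic single-cell population for a
#' preset gene under a protocol, extract the per-cell feature table,
#' and (for a two-pulse protocol) the responder contingency table. All
#' outputs plus a manifest recording the seed, parameters and file list
#' are written under \code{outdir}; rerunning with the same config
#' reproduces every output.
#'
#' @param config list with elements \code{gene} (preset name),
#'   \code{protocol} (shorthand string), \code{n_cells}, \code{seed},
#'   \code{outdir}, and optionally \code{noise} (a [noise_model()]),
#'   \code{horizon}.
#' @return Invisibly, a list with the trace matrix, feature table,
#'   optional two-pulse summary, and output paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(is.list(config), !is.null(config$gene), !is.null(config$outdir))
  gene <- config$gene
  protocol <- parse_protocol(config$protocol %||% "constant:10",
                             horizon = config$horizon %||% 31)
  n_cells <- config$n_cells %||% 200
  seed <- config$seed %||% 1
  noise <- config$noise %||% noise_model()
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)

  kin <- preset_kinetics(gene)
  adapt <- preset_adaptation()
  tm <- gen_population(kin, adapt, protocol, n_cells = n_cells,
                       noise = noise, seed = seed,
                       horizon = config$horizon %||% 31)
  traces_path <- file.path(config$outdir, "traces.csv")
  write_traces(tm, traces_path)

  feats <- extract_features(tm, tanh_features = identical(gene, "CXCL10"))
  feats_path <- file.path(config$outdir, "features.csv")
  utils::write.csv(feats, feats_path, row.names = FALSE)

  out <- list(traces = tm, features = feats,
              paths = list(traces = traces_path, features = feats_path))

  if (nrow(protocol$segments) == 2) {
    seg <- protocol$segments
    amp <- sapply(1:2, function(p)
      apply(tm$values, 1, function(tr)
        pulse_amplitude_window(tr, tm$time, seg$t_start[p], seg$t_end[p],
                               mode = "experimental")))
    cls <- classify_responders(amp, responder_threshold(tm))
    tp_path <- file.path(config$outdir, "responders.csv")
    utils::write.csv(as.data.frame(cls$contingency), tp_path,
                     row.names = FALSE)
    out$two_pulse <- cls
    out$paths$responders <- tp_path
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("ifngdyn")),
    gene = gene, seed = seed, n_cells = n_cells,
    protocol = protocol$segments, horizon = protocol$horizon,
    noise = unclass(noise),
    kinetics = unclass(kin), adaptation = unclass(adapt),
    outputs = unlist(out$paths))
  manifest_path <- file.path(config$outdir, "manifest.yml")
  yaml::write_yaml(manifest, manifest_path)
  out$paths$manifest <- manifest_path
  invisible(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
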