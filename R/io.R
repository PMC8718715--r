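#' @include utils.R
NULL

#' Write / read an excitation movie as multi-page float TIFF
#'
#' Frames are stored as 32-bit float pages. Because float TIFF payloads must
#' lie in [0, 1], values are affinely packed using the global range, which is
#' recorded (with dimensions and mask) in a JSON sidecar \code{<path>.json};
#' reading applies the inverse map. Round trips are exact at float32
#' precision.
#'
#' @param movie \linkS4class{ExcitationMovie} or array.
#' @param path output .tif path.
#' @return invisibly, the path.
#' @export
writeMovieTIFF <- function(movie, path) {
  movie <- asMovie(movie)
  fr <- movie@frames
  lo <- min(fr); hi <- max(fr)
  scale <- if (hi > lo) hi - lo else 1
  packed <- (fr - lo) / scale
  pages <- lapply(seq_len(dim(fr)[3]), function(t) packed[, , t])
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  side <- list(kind = "excitation", lo = lo, hi = hi, dims = dim(fr),
               mask = if (is.null(movie@mask)) NULL else which(!movie@mask))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname writeMovieTIFF
#' @return for the reader, an \linkS4class{ExcitationMovie}.
#' @export
readMovieTIFF <- function(path) {
  side <- readSidecar(path, "excitation")
  pages <- tiff::readTIFF(path, all = TRUE)
  d <- as.integer(unlist(side$dims))
  fr <- array(0, d)
  for (t in seq_len(d[3])) fr[, , t] <- pages[[t]]
  fr <- fr * (side$hi - side$lo) + side$lo
  if (side$hi <= side$lo) fr[] <- side$lo
  mask <- NULL
  if (!is.null(side$mask)) {
    mask <- matrix(TRUE, d[1], d[2])
    mask[as.integer(unlist(side$mask))] <- FALSE
    fr[rep(!mask, d[3])] <- 0
  }
  new("ExcitationMovie", frames = fr, mask = mask,
      meta = list(source = path))
}

readSidecar <- function(path, kind) {
  sp <- paste0(path, ".json")
  if (!file.exists(sp))
    stop("missing sidecar file: ", sp)
  side <- jsonlite::read_json(sp)
  if (!identical(side$kind, kind))
    stop("sidecar field 'kind': expected '", kind, "', found '",
         side$kind, "'")
  side
}

#' Write / read a phase movie as multi-page float TIFF
#'
#' Phases are packed as (phi + pi) / (2 pi) into [0, 1); missing values are
#' stored as the sentinel 1.0 (unreachable for valid phases, which are
#' clamped just below 1). A JSON sidecar records dimensions and mask.
#' Round trips are exact at the 32-bit packing precision (well below
#' 1e-5 rad).
#'
#' @param phase \linkS4class{PhaseMovie} or phase array.
#' @param path output .tif path.
#' @return invisibly, the path.
#' @export
writePhaseTIFF <- function(phase, path) {
  p <- asPhaseArray(phase)
  packed <- (p$ph + pi) / (2 * pi)
  packed <- pmin(packed, 1 - 1e-6)
  packed[is.na(packed)] <- 1
  dim(packed) <- dim(p$ph)
  pages <- lapply(seq_len(dim(packed)[3]), function(t) packed[, , t])
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  side <- list(kind = "phase", dims = dim(p$ph),
               mask = if (is.null(p$mask)) NULL else which(!p$mask))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname writePhaseTIFF
#' @return for the reader, a \linkS4class{PhaseMovie}.
#' @export
readPhaseTIFF <- function(path) {
  side <- readSidecar(path, "phase")
  pages <- tiff::readTIFF(path, all = TRUE)
  d <- as.integer(unlist(side$dims))
  ph <- array(NaN, d)
  for (t in seq_len(d[3])) {
    pg <- pages[[t]]
    v <- pg * 2 * pi - pi
    # the sentinel 1.0 may come back minutely below 1 after TIFF quantization
    v[pg >= 1 - 1e-7] <- NaN
    ph[, , t] <- v
  }
  mask <- NULL
  if (!is.null(side$mask)) {
    mask <- matrix(TRUE, d[1], d[2])
    mask[as.integer(unlist(side$mask))] <- FALSE
    ph[rep(!mask, d[3])] <- NaN
  }
  new("PhaseMovie", phases = ph, mask = mask, meta = list(source = path))
}

#' Write / read phase singularity sets as CSV
#'
#' Columns t, x, y, chirality; coordinates written with 6 decimals, so round
#' trips are exact at that precision.
#'
#' @param ps a \linkS4class{PhaseSingularitySet}.
#' @param path output .csv path.
#' @return invisibly, the path.
#' @export
writePSCSV <- function(ps, path) {
  p <- ps@points
  p$x <- sprintf("%.6f", p$x)
  p$y <- sprintf("%.6f", p$y)
  utils::write.csv(p, path, row.names = FALSE, quote = FALSE)
  side <- list(kind = "ps", dims = ps@dims, nFrames = ps@nFrames)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writePSCSV
#' @param dims,nFrames image dims and frame count when no sidecar exists.
#' @return for the reader, a \linkS4class{PhaseSingularitySet}.
#' @export
readPSCSV <- function(path, dims = NULL, nFrames = NULL) {
  p <- utils::read.csv(path)
  need <- c("t", "x", "y", "chirality")
  missingCols <- setdiff(need, names(p))
  if (length(missingCols))
    stop("malformed PS CSV, missing column(s): ",
         paste(missingCols, collapse = ", "))
  sp <- paste0(path, ".json")
  if (file.exists(sp)) {
    side <- jsonlite::read_json(sp)
    dims <- as.integer(unlist(side$dims))
    nFrames <- as.integer(side$nFrames)
  }
  if (is.null(dims) || is.null(nFrames))
    stop("dims and nFrames required (no sidecar found)")
  newPSSet(p[need], dims, nFrames)
}

simConfigKeys <- c("gridSize", "a", "k", "eps0", "mu1", "mu2", "D", "dt",
                   "dx", "stencil", "snapshotStride", "nSnapshots",
                   "transientTime", "s1Width", "s2Time", "s2Rows", "s2Cols",
                   "nRandomStims", "stimWindow", "stimRadius",
                   "stimAmplitude", "seed")

#' Read / write a simulation configuration as YAML
#'
#' Unknown keys are rejected by name; missing keys take the package defaults.
#'
#' @param path .yaml path.
#' @return a \linkS4class{SimulationConfig}.
#' @export
readConfigYAML <- function(path) {
  vals <- yaml::read_yaml(path)
  unknown <- setdiff(names(vals), simConfigKeys)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  int <- c("gridSize", "stencil", "snapshotStride", "nSnapshots", "s1Width",
           "nRandomStims", "seed")
  for (k in intersect(int, names(vals)))
    vals[[k]] <- as.integer(unlist(vals[[k]]))
  for (k in setdiff(names(vals), int)) vals[[k]] <- unlist(vals[[k]])
  do.call(simulationConfig, vals)
}

#' @rdname readConfigYAML
#' @param config a \linkS4class{SimulationConfig} to write.
#' @export
writeConfigYAML <- function(config, path) {
  vals <- lapply(simConfigKeys, function(k) slot(config, k))
  names(vals) <- simConfigKeys
  yaml::write_yaml(vals, path)
  invisible(path)
}

#' Write / read an evaluation report as JSON
#'
#' The report schema is versioned; arbitrary numeric/list entries round-trip.
#'
#' @param report named list of metrics.
#' @param path .json path.
#' @return invisibly, the path.
#' @export
writeMetricsJSON <- function(report, path) {
  out <- c(list(schema = "rotormap-metrics-1"), report)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' @rdname writeMetricsJSON
#' @return for the reader, the report list.
#' @export
readMetricsJSON <- function(path) {
  rep <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(rep$schema, "rotormap-metrics-1"))
    stop("unrecognized metrics schema field: ", rep$schema)
  rep$schema <- NULL
  rep
}

#' Save / load a dataset container
#'
#' Serializes a \linkS4class{RotorDataset} (inputs, targets, masks,
#' provenance) to a single RDS file.
#'
#' @param dataset a \linkS4class{RotorDataset}.
#' @param path output .rds path.
#' @return invisibly, the path.
#' @export
saveDataset <- function(dataset, path) {
  saveRDS(dataset, path)
  invisible(path)
}

#' @rdname saveDataset
#' @return for the loader, the \linkS4class{RotorDataset}.
#' @export
loadDataset <- function(path) {
  x <- readRDS(path)
  if (!is(x, "RotorDataset")) stop("file does not contain a RotorDataset")
  x
}

#' Save / load a trained model
#'
#' Serializes a \linkS4class{RotorNet} with a JSON sidecar describing the
#' architecture and training provenance.
#'
#' @param net a \linkS4class{RotorNet}.
#' @param path output .rds path.
#' @return invisibly, the path.
#' @export
saveModel <- function(net, path) {
  saveRDS(net, path)
  side <- list(kind = "rotornet", variant = net@variant,
               spec = net@spec[c("inputFrames", "side", "encoderWidths",
                                 "latentWidth", "convsPerStage", "head")],
               epochs = nrow(net@state$history %||% data.frame()))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname saveModel
#' @return for the loader, the \linkS4class{RotorNet}.
#' @export
loadModel <- function(path) {
  x <- readRDS(path)
  if (!is(x, "RotorNet")) stop("file does not contain a RotorNet")
  x
}
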