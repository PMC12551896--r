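#' @include AllClasses.R
NULL

#' Read a grayscale stimulus image
#'
#' `readImagePNG` reads an 8- or 16-bit PNG; color images are converted
#' to grayscale with ITU-R 601 luminance weights (0.299, 0.587, 0.114).
#' `readImageMatrix` reads a whitespace-delimited plain-text matrix.
#' Values are clamped to \[0,1\].
#'
#' @param path file path.
#' @return numeric matrix in \[0,1\].
#' @export
readImagePNG <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 3) {
    if (dim(x)[3] >= 3)
      x <- 0.299 * x[, , 1] + 0.587 * x[, , 2] + 0.114 * x[, , 3]
    else x <- x[, , 1]
  }
  pmin(pmax(x, 0), 1)
}

#' @rdname readImagePNG
#' @export
readImageMatrix <- function(path) {
  rows <- readLines(path)
  rows <- rows[nzchar(trimws(rows))]
  vals <- lapply(strsplit(trimws(rows), "[[:space:]]+"), as.numeric)
  m <- do.call(rbind, vals)
  pmin(pmax(m, 0), 1)
}

#' Write a grayscale image as PNG
#'
#' @param image numeric matrix in \[0,1\].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeImagePNG <- function(image, path) {
  png::writePNG(pmin(pmax(image, 0), 1), path)
  invisible(path)
}

#' Serialize a stimulus set to a directory of PNGs plus a manifest
#'
#' Writes every stimulus as `<id>.png` and a `manifest.csv` with
#' columns (stimulus_id, target_id, level, sample, seed).
#'
#' @param set a [StimulusSet-class].
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
writeStimulusSet <- function(set, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  info <- stimulusInfo(set)
  for (i in info$index)
    writeImagePNG(set@stimuli[[i]]$pixels,
                  file.path(dir, paste0(info$stimulusId[i], ".png")))
  manifest <- data.frame(stimulus_id = info$stimulusId,
                         target_id = info$targetId,
                         level = info$level, sample = info$sample,
                         seed = vapply(set@stimuli, function(s)
                           as.integer(s$seed), integer(1)))
  path <- file.path(dir, "manifest.csv")
  write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' Dictionary checkpoints as portable JSON
#'
#' Plain-text array container with fields `filters` (row-major),
#' `filter_side`, `n_filters`, `stride`, `norm_flag`, `seed`; lets an
#' experiment fix pre-trained filters across runs.
#'
#' @param dict a [SparseDictionary-class].
#' @param path output / input path.
#' @return `writeDictionary`: the path, invisibly; `readDictionary`:
#'   the [SparseDictionary-class].
#' @export
writeDictionary <- function(dict, path) {
  jsonlite::write_json(list(
    filters = as.numeric(dict@filters),
    filter_side = dict@filterSide,
    n_filters = ncol(dict@filters),
    stride = dict@stride,
    norm_flag = all(abs(colSums(dict@filters^2) - 1) < 1e-8),
    seed = dict@seed), path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeDictionary
#' @export
readDictionary <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("SparseDictionary",
      filters = matrix(x$filters, x$filter_side^2, x$n_filters),
      filterSide = as.integer(x$filter_side),
      stride = as.integer(x$stride), seed = as.integer(x$seed),
      objective = numeric(0))
}

#' Connectivity checkpoints as portable JSON
#'
#' Stores the plastic E-E weights as sparse triplets together with the
#' support mask triplets and the generating configuration; the fixed
#' E-I/I-E matrices are rebuilt from the configuration on load.
#'
#' @param conn a [Connectivity-class].
#' @param path output / input path.
#' @return `writeConnectivity`: the path, invisibly;
#'   `readConnectivity`: the [Connectivity-class].
#' @export
writeConnectivity <- function(conn, path) {
  nz <- which(conn@Wee != 0, arr.ind = TRUE)
  cfg <- conn@config
  jsonlite::write_json(list(
    i = nz[, 1], j = nz[, 2], x = conn@Wee[nz],
    config = list(nRows = cfg@nRows, nCols = cfg@nCols,
                  nChannels = cfg@nChannels, radiusE = cfg@radiusE,
                  radiusI = cfg@radiusI, wEE = cfg@wEE, wIE = cfg@wIE,
                  tauE = cfg@tauE, tauI = cfg@tauI, dt = cfg@dt,
                  inputScale = cfg@inputScale,
                  divergenceBound = cfg@divergenceBound)),
    path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeConnectivity
#' @export
readConnectivity <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(networkConfig, as.list(x$config))
  conn <- buildConnectivity(cfg)
  Wee <- matrix(0, nrow(conn@Wee), ncol(conn@Wee))
  Wee[cbind(x$i, x$j)] <- x$x
  conn@Wee <- Wee
  validObject(conn)
  conn
}

#' Export E-E row sums for audit
#'
#' Writes a CSV of per-neuron total presynaptic E-E weight, the
#' quantity the synaptic-resource normalization conserves.
#'
#' @param conn a [Connectivity-class].
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
writeRowSums <- function(conn, path) {
  write.csv(data.frame(neuron = seq_len(nrow(conn@Wee)),
                       rowSum = rowSums(conn@Wee)),
            path, row.names = FALSE)
  invisible(path)
}
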