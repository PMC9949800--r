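#' @importFrom jsonlite read_json write_json
#' @importFrom utils read.csv write.csv
NULL

SCHEMA_VERSION <- "1.0"

checkSchema <- function(meta, path) {
  v <- meta$schema_version
  if (!is.null(v)) {
    major <- as.integer(strsplit(as.character(v), ".", fixed = TRUE)[[1]][1])
    if (is.finite(major) && major > 1L)
      stop(sprintf("%s: schema version %s is newer than supported (1.x)",
                   path, v))
  }
  invisible(TRUE)
}

#' Write / read a TraceSet as CSV plus JSON sidecar
#'
#' The CSV holds one column per cell (header row of cell ids) and one row
#' per frame, numbers serialised with 17 significant digits. The sidecar
#' JSON carries \code{dt} (seconds), \code{stim_frame} (0-based index of
#' the first post-stimulus frame, the on-disk convention), \code{units}
#' and \code{schema_version}. The reader converts \code{stim_frame} back
#' to the package's 1-based \code{stimFrame}.
#'
#' @param ts a \linkS4class{TraceSet}.
#' @param path CSV file path.
#' @param metaPath sidecar JSON path (default: \code{path} with
#'   \code{.json} appended).
#' @return \code{writeTraceCSV}: the paths, invisibly.
#'   \code{readTraceCSV}: a \linkS4class{TraceSet}.
#' @export
writeTraceCSV <- function(ts, path, metaPath = paste0(path, ".json")) {
  v <- traceValues(ts)
  df <- as.data.frame(signif(v, 17))
  names(df) <- cellIds(ts)
  write.csv(df, path, row.names = FALSE)
  write_json(list(schema_version = SCHEMA_VERSION,
                  dt = frameInterval(ts),
                  stim_frame = stimFrame(ts) - 1L,
                  units = "ratio"),
             metaPath, auto_unbox = TRUE, digits = NA)
  invisible(c(path, metaPath))
}

#' @rdname writeTraceCSV
#' @export
readTraceCSV <- function(path, metaPath = paste0(path, ".json")) {
  if (!file.exists(metaPath))
    stop(sprintf("missing sidecar JSON '%s' (needs dt and stim_frame)", metaPath))
  meta <- read_json(metaPath)
  checkSchema(meta, metaPath)
  for (f in c("dt", "stim_frame"))
    if (is.null(meta[[f]]))
      stop(sprintf("sidecar '%s' is missing required field '%s'", metaPath, f))
  df <- read.csv(path, check.names = FALSE)
  m <- as.matrix(df)
  if (!is.numeric(m)) stop(sprintf("'%s' contains non-numeric trace values", path))
  bad <- which(!is.finite(m), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("non-finite trace value at row %d, column '%s' of '%s'",
                 bad[1, 1], colnames(m)[bad[1, 2]], path))
  TraceSet(m, stimFrame = as.integer(meta$stim_frame) + 1L,
           dt = as.numeric(meta$dt), cellIds = colnames(m))
}

#' Write / read a force curve as CSV plus probe-metadata JSON
#'
#' The CSV has exactly the columns \code{z_um} and \code{deflection_nm}
#' (the header carries the units and is checked bit-exactly); the probe
#' JSON carries \code{k_N_per_m}, \code{R_um}, \code{nu}. On read, a
#' non-monotone z is sorted ascending with a warning, or rejected when
#' \code{strict = TRUE}.
#'
#' @param curve a \linkS4class{ForceCurve}.
#' @param path CSV file path.
#' @param metaPath probe JSON path (default: \code{path} with \code{.json}
#'   appended).
#' @param strict reject non-monotone z instead of sorting (default FALSE).
#' @return \code{writeForceCurveCSV}: the paths, invisibly.
#'   \code{readForceCurve}: a \linkS4class{ForceCurve}.
#' @export
writeForceCurveCSV <- function(curve, path, metaPath = paste0(path, ".json")) {
  df <- data.frame(z_um = signif(curve@z, 17),
                   deflection_nm = signif(curve@deflection, 17))
  write.csv(df, path, row.names = FALSE)
  write_json(list(schema_version = SCHEMA_VERSION, k_N_per_m = curve@k,
                  R_um = curve@R, nu = curve@nu),
             metaPath, auto_unbox = TRUE, digits = NA)
  invisible(c(path, metaPath))
}

#' @rdname writeForceCurveCSV
#' @export
readForceCurve <- function(path, metaPath = paste0(path, ".json"),
                           strict = FALSE) {
  if (!file.exists(metaPath))
    stop(sprintf("missing probe JSON '%s' (needs k_N_per_m, R_um, nu)", metaPath))
  meta <- read_json(metaPath)
  checkSchema(meta, metaPath)
  for (f in c("k_N_per_m", "R_um", "nu"))
    if (is.null(meta[[f]]))
      stop(sprintf("probe JSON '%s' is missing required field '%s'", metaPath, f))
  df <- read.csv(path, check.names = FALSE)
  want <- c("z_um", "deflection_nm")
  if (!identical(names(df)[1:2], want))
    stop(sprintf(
      "'%s': expected columns 'z_um, deflection_nm' (micrometres, nanometres) but found '%s' — check the unit suffixes",
      path, paste(names(df)[1:2], collapse = ", ")))
  z <- df$z_um; d <- df$deflection_nm
  if (any(diff(z) <= 0)) {
    if (strict) stop(sprintf("'%s': z_um is not strictly increasing", path))
    warning(sprintf("'%s': z_um not strictly increasing; sorting ascending", path))
    ord <- order(z)
    z <- z[ord]; d <- d[ord]
    keep <- !duplicated(z)
    z <- z[keep]; d <- d[keep]
  }
  ForceCurve(z, d, k = as.numeric(meta$k_N_per_m), R = as.numeric(meta$R_um),
             nu = as.numeric(meta$nu))
}

#' Read a per-cell whole-cell recording table
#'
#' Expects columns \code{cell}, \code{line}, \code{condition}, \code{V_mV}
#' and either \code{density_pA_pF} or both \code{I_pA} and \code{C_pF}
#' (densities are then computed). Returns one
#' \linkS4class{EphysGroup} per line x condition x voltage.
#'
#' @param path CSV path.
#' @return Named list of \linkS4class{EphysGroup} (names
#'   \code{"line:condition:V"}).
#' @export
readEphysCSV <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  need <- c("cell", "line", "condition", "V_mV")
  if (!all(need %in% names(df)))
    stop(sprintf("'%s' must contain columns %s", path,
                 paste(need, collapse = ", ")))
  if (!"density_pA_pF" %in% names(df)) {
    if (!all(c("I_pA", "C_pF") %in% names(df)))
      stop(sprintf("'%s' needs density_pA_pF, or I_pA and C_pF", path))
    df$density_pA_pF <- currentDensity(df$I_pA, df$C_pF)
  }
  key <- paste(df$line, df$condition, df$V_mV, sep = ":")
  out <- lapply(split(df, key), function(d) {
    EphysGroup(paste(d$line[1], d$condition[1], sep = ":"), d$V_mV[1],
               density = d$density_pA_pF)
  })
  out
}

#' Write / read a two-channel stack as multi-page TIFFs
#'
#' One file per channel. Intensities are stored as 16-bit samples after
#' scaling by the stack maximum; the scale factors live in a sidecar JSON
#' so reads restore the original values (to 16-bit quantisation).
#'
#' @param pair an \linkS4class{ImageStackPair}.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix (default "stack").
#' @return \code{writeStackTIFF}: paths, invisibly. \code{readStackTIFF}:
#'   an \linkS4class{ImageStackPair}.
#' @export
writeStackTIFF <- function(pair, dir, prefix = "stack") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gPath <- file.path(dir, paste0(prefix, "_green.tif"))
  rPath <- file.path(dir, paste0(prefix, "_red.tif"))
  mPath <- file.path(dir, paste0(prefix, "_meta.json"))
  gMax <- max(pair@green, 1e-12)
  rMax <- max(pair@red, 1e-12)
  asPages <- function(a, mx) lapply(seq_len(dim(a)[3]),
                                    function(t) a[, , t] / mx)
  tiff::writeTIFF(asPages(pair@green, gMax), gPath, bits.per.sample = 16L)
  tiff::writeTIFF(asPages(pair@red, rMax), rPath, bits.per.sample = 16L)
  meta <- list(schema_version = SCHEMA_VERSION, green_max = gMax,
               red_max = rMax)
  if (is.finite(pair@pixelSize)) meta$pixel_size_um <- pair@pixelSize
  write_json(meta, mPath, auto_unbox = TRUE, digits = NA)
  invisible(c(gPath, rPath, mPath))
}

#' @rdname writeStackTIFF
#' @param greenPath,redPath per-channel TIFF paths.
#' @param metaPath sidecar JSON with the intensity scale factors.
#' @export
readStackTIFF <- function(greenPath, redPath, metaPath) {
  meta <- read_json(metaPath)
  checkSchema(meta, metaPath)
  toArray <- function(pages, mx) {
    a <- array(0, c(dim(pages[[1]])[1], dim(pages[[1]])[2], length(pages)))
    for (t in seq_along(pages)) a[, , t] <- pages[[t]] * mx
    a
  }
  g <- tiff::readTIFF(greenPath, all = TRUE)
  r <- tiff::readTIFF(redPath, all = TRUE)
  ps <- meta$pixel_size_um
  ImageStackPair(toArray(g, meta$green_max), toArray(r, meta$red_max),
                 pixelSize = if (is.null(ps)) NA_real_ else as.numeric(ps))
}

#' Write a label image as 16-bit TIFF
#'
#' @param seg a \linkS4class{SegmentationResult}.
#' @param path output TIFF path.
#' @return The path, invisibly.
#' @export
writeLabelTIFF <- function(seg, path) {
  tiff::writeTIFF(labelImage(seg) / 65535, path, bits.per.sample = 16L)
  invisible(path)
}
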