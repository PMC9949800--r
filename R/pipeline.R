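#' Run the full analysis pipeline from a configuration
#'
#' Executes the requested stages on synthetic data generated from the
#' configured parameters, writing per-stage outputs, a resolved copy of the
#' configuration and a JSON run report next to them. Every output is
#' reproducible from (config, seed) alone. Stages:
#' \describe{
#'   \item{traces}{\code{\link{genTraces}} -> \code{\link{analyzeTraces}}
#'     -> \code{\link{summarizeTraces}}; writes traces CSV + sidecar,
#'     per-cell results CSV and a summary JSON.}
#'   \item{imaging}{\code{\link{genImageStack}} ->
#'     \code{\link{ratioStack}} -> \code{\link{segmentCells}} ->
#'     \code{\link{extractTraces}} -> \code{\link{analyzeTraces}}; writes
#'     channel TIFFs, the label TIFF and per-cell results CSV.}
#'   \item{indent}{\code{\link{makeGrid}} + \code{\link{genForceCurve}}
#'     per site -> \code{\link{analyzeMap}}; writes the fits CSV and map
#'     summary JSON.}
#'   \item{ephys}{\code{\link{genEphysGroups}} ->
#'     \code{\link{deltaCurrent}} and \code{\link{genPatchTrace}} ->
#'     \code{\link{unitaryCurrent}}; writes a delta summary CSV and a
#'     unitary-current JSON.}
#' }
#'
#' @param config nested list (or path to a JSON/YAML file) with optional
#'   blocks \code{traces}, \code{imaging}, \code{indent}, \code{ephys}
#'   holding stage parameters (arguments of the respective generators),
#'   plus top-level \code{stages} (character vector, default: all blocks
#'   present), \code{seed} (integer, default 1). Unknown top-level keys are
#'   rejected.
#' @param outDir output directory.
#' @return The run report (list), invisibly; also written as
#'   \code{report.json}.
#' @examples
#' \donttest{
#' rep <- runPipeline(list(seed = 1,
#'                         traces = list(nCells = 20, responderFrac = 0.5,
#'                                       nPre = 20, nPost = 60)),
#'                    outDir = tempfile("run"))
#' rep$stages$traces$summary$responderFrac
#' }
#' @export
runPipeline <- function(config, outDir) {
  if (is.character(config) && length(config) == 1) {
    config <- if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config)
              else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  known <- c("stages", "seed", "traces", "imaging", "indent", "ephys")
  unknown <- setdiff(names(config), known)
  if (length(unknown))
    stop(sprintf("unknown configuration key(s): %s",
                 paste(unknown, collapse = ", ")))
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  stages <- if (!is.null(config$stages)) config$stages
            else intersect(names(config), c("traces", "imaging", "indent", "ephys"))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)

  report <- list(package = "calcimech",
                 version = as.character(utils::packageVersion("calcimech")),
                 seed = seed, stages = list(), warnings = list())

  runStage <- function(name, fn) {
    res <- tryCatch(fn(), error = function(e) {
      writeReport(report, outDir)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    report$stages[[name]] <<- res
  }

  if ("traces" %in% stages) runStage("traces", function() {
    args <- config$traces; args$seed <- seed
    g <- do.call(genTraces, args)
    writeTraceCSV(g$traces, file.path(outDir, "traces.csv"))
    res <- analyzeTraces(g$traces)
    write.csv(res, file.path(outDir, "trace_results.csv"), row.names = FALSE)
    s <- summarizeTraces(res)
    write_json(s, file.path(outDir, "trace_summary.json"),
               auto_unbox = TRUE, digits = NA)
    list(nCells = s$nCells, responderFrac = s$responderFrac, summary = s)
  })

  if ("imaging" %in% stages) runStage("imaging", function() {
    args <- config$imaging; args$seed <- seed
    g <- do.call(genImageStack, args)
    writeStackTIFF(g$stack, outDir)
    ratio <- ratioStack(g$stack)
    seg <- segmentCells(g$stack,
                        minArea = if (is.null(args$minArea)) 100 else args$minArea)
    writeLabelTIFF(seg, file.path(outDir, "labels.tif"))
    ts <- extractTraces(ratio, seg, stimFrame(g$truth$traces),
                        frameInterval(g$truth$traces))
    res <- analyzeTraces(ts)
    write.csv(res, file.path(outDir, "imaging_results.csv"), row.names = FALSE)
    list(nCellsTrue = max(g$truth$labels), nCellsFound = length(labelAreas(seg)),
         responderFrac = mean(res$responder))
  })

  if ("indent" %in% stages) runStage("indent", function() {
    args <- config$indent
    grid <- makeGrid(side = args$side %||% 10, spacing = args$spacing %||% 0.5)
    E <- args$E %||% 15
    curves <- lapply(seq_len(nrow(grid)), function(i)
      genForceCurve(E = E, noiseSigma = args$noiseSigma %||% 1,
                    seed = seed + i)$curve)
    map <- analyzeMap(curves, coords = grid)
    write.csv(map$fits, file.path(outDir, "hertz_fits.csv"), row.names = FALSE)
    write_json(map$summary, file.path(outDir, "hertz_summary.json"),
               auto_unbox = TRUE, digits = NA)
    map$summary
  })

  if ("ephys" %in% stages) runStage("ephys", function() {
    args <- config$ephys
    specs <- if (!is.null(args$specs)) as.data.frame(args$specs)
             else data.frame(label = c("basal", "inhibited"),
                             mean = c(50.13, 13.8), sd = c(5, 5),
                             n = c(30, 30), voltage = -70)
    g <- genEphysGroups(specs, seed = seed)
    d <- deltaCurrent(g$groups[[1]], g$groups[[2]])
    write.csv(data.frame(delta_pA_pF = d$delta),
              file.path(outDir, "delta.csv"), row.names = FALSE)
    p <- genPatchTrace(seed = seed)
    u <- unitaryCurrent(p$trace$I_pA)
    write_json(list(delta_mean = d$mean, delta_sem = d$sem,
                    unitary_pA = u$iU, unitary_status = u$status),
               file.path(outDir, "ephys_summary.json"),
               auto_unbox = TRUE, digits = NA)
    list(deltaMean = d$mean, unitary = u$iU)
  })

  write_json(config, file.path(outDir, "resolved_config.json"),
             auto_unbox = TRUE, digits = NA, null = "null")
  writeReport(report, outDir)
  invisible(report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

writeReport <- function(report, outDir) {
  write_json(report, file.path(outDir, "report.json"),
             auto_unbox = TRUE, digits = NA, force = TRUE, null = "null")
}
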