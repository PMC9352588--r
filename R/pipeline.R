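.defaultConfig <- function() list(
  seed = 1,
  behavior = list(chunk_s = 300, n_shifts = 10, map_extent_mm = 60,
                  map_bin_mm = 1, smooth_sigma_mm = 3, n_scans = 24,
                  scan_length_mm = 29, loom_post_s = 1, loom_pre_s = 1.3),
  neural = list(baseline_s = 5, percentile = 95, bpi_threshold = 0.5,
                bout_hz = c(0.75, 1.5, 3), cont_hz = c(6, 60)),
  anatomy = list(bandwidth_um = 10, spacing_um = 2,
                 contour_levels = c(0.1, 0.15, 0.3)),
  cfos = list(baseline = "no-stimulus", var_equal = TRUE)
)

.mergeConfig <- function(user, defaults, where = "config") {
  if (is.null(user)) return(defaults)
  bad <- setdiff(names(user), c(names(defaults), "inputs", "simulate"))
  if (length(bad))
    stop("unknown ", where, " key(s): ", paste(bad, collapse = ", "))
  for (k in names(user)) {
    defaults[[k]] <- if (is.list(defaults[[k]]) && is.list(user[[k]]))
      .mergeConfig(user[[k]], defaults[[k]], paste0(where, "$", k))
    else user[[k]]
  }
  defaults
}

#' Run the analysis pipeline from a configuration
#'
#' Executes the requested stages (`behavior`, `neural`, `anatomy`,
#' `cfos`) on inputs that are either read from files or generated by the
#' synthetic module, writes result tables (CSV) and a JSON report
#' recording the resolved configuration, package version and seed into
#' `outDir`. Parameter defaults are the study's standard values (5 min
#' chunks, 10 time shifts, 3 mm map smoothing, 24 scans over 29 mm, 5 s
#' dF/F baseline, 95th-percentile responsiveness, BPI threshold 0.5,
#' 10 um KDE bandwidth, contour levels 0.1/0.15/0.3 per 1000 um^3,
#' Bonferroni alpha/3). Unknown configuration keys are rejected. Reruns
#' with the same seed produce identical tables; on error, files written
#' during the failed run are removed.
#'
#' @param config a nested list (or path to a JSON file) selecting stages
#'   and overriding defaults; each requested stage needs either an
#'   `inputs` entry (file paths) or a `simulate` stanza.
#' @param outDir output directory (created if missing).
#' @return Invisibly, a list of the per-stage results.
#' @export
runPipeline <- function(config, outDir) {
  if (is.character(config))
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  cfg <- .mergeConfig(config, .defaultConfig())
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  emit <- function(name, writer) {
    path <- file.path(outDir, name)
    writer(path)
    written <<- c(written, path)
    path
  }
  results <- list()
  ok <- FALSE
  on.exit(if (!ok) unlink(written))
  stages <- intersect(names(config), c("behavior", "neural", "anatomy", "cfos"))
  for (stage in stages) {
    st <- config[[stage]]
    res <- switch(stage,
      behavior = .stageBehavior(st, cfg$behavior, cfg$seed, emit),
      neural = .stageNeural(st, cfg$neural, cfg$seed, emit),
      anatomy = .stageAnatomy(st, cfg$anatomy, cfg$seed, emit),
      cfos = .stageCfos(st, cfg$cfos, cfg$seed, emit))
    results[[stage]] <- res
  }
  report <- list(package = "ShoalVision",
                 version = as.character(packageVersion("ShoalVision")),
                 seed = cfg$seed, stages = stages,
                 config = cfg[c("seed", stages)])
  emit("report.json", function(p)
    jsonlite::write_json(report, p, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE))
  ok <- TRUE
  invisible(results)
}

.stageBehavior <- function(st, prm, seed, emit) {
  if (!is.null(st$inputs)) {
    if (!file.exists(st$inputs$focal %||% "") ||
        !file.exists(st$inputs$neighbor %||% ""))
      stop("behavior stage: missing input track file")
    focal <- readTrack(st$inputs$focal)
    neighbor <- readTrack(st$inputs$neighbor)
  } else if (!is.null(st$simulate)) {
    sim <- do.call(genDyad, modifyList(list(seed = seed),
                                       as.list(st$simulate)))
    focal <- sim$focal; neighbor <- sim$neighbor
  } else stop("behavior stage: provide inputs or a simulate stanza")
  att <- attractionAnalysis(focal, neighbor, chunkS = prm$chunk_s,
                            nShifts = prm$n_shifts)
  map <- neighborDensityMap(focal, neighbor, extentMm = prm$map_extent_mm,
                            binMm = prm$map_bin_mm)
  rep <- repulsionScore(map, sigmaMm = prm$smooth_sigma_mm,
                        nScans = prm$n_scans,
                        maxRadiusMm = prm$scan_length_mm)
  bouts <- detectBouts(focal)
  out <- list(attraction = meanAttraction(att),
              iad_real_mm = mean(att@iadReal),
              iad_shifted_mm = mean(att@iadShifted),
              repulsion_score = rep@score, r_peak_mm = rep@rPeak,
              bout_rate_hz = nrow(bouts) / diff(range(focal@t)))
  emit("behavior.json", function(p)
    jsonlite::write_json(out, p, auto_unbox = TRUE, digits = NA))
  emit("neighbor_map.csv", function(p)
    utils::write.table(map@counts, p, sep = ",", row.names = FALSE,
                       col.names = FALSE))
  out
}

.stageNeural <- function(st, prm, seed, emit) {
  if (!is.null(st$inputs)) {
    if (!file.exists(st$inputs$traces %||% ""))
      stop("neural stage: missing input trace file")
    traces <- readTraceMatrix(st$inputs$traces)
    schedule <- readStimulusSchedule(st$inputs$schedule)
  } else if (!is.null(st$simulate)) {
    sim <- genTraces(do.call(neuronSimParams, as.list(st$simulate)),
                     seed = seed)
    traces <- sim$traces
    schedule <- makeFrequencySchedule()
  } else stop("neural stage: provide inputs or a simulate stanza")
  ep <- epochDFF(traces, schedule, baselineS = prm$baseline_s)
  rt <- meanResponses(ep)
  keep <- responsiveFilter(rt, percentile = prm$percentile)
  bpi <- boutPreferenceIndex(rt[keep, ], boutHz = prm$bout_hz,
                             contHz = prm$cont_hz,
                             threshold = prm$bpi_threshold)
  out <- list(n_roi = nrow(responseValues(rt)), n_responsive = length(keep),
              n_bpn = sum(bpi$bpn), bpn_fraction = mean(bpi$bpn))
  emit("responses.csv", function(p)
    write.csv(responseValues(rt), p))
  emit("bpi.csv", function(p) write.csv(bpi, p, row.names = FALSE))
  emit("neural.json", function(p)
    jsonlite::write_json(out, p, auto_unbox = TRUE, digits = NA))
  out
}

.stageAnatomy <- function(st, prm, seed, emit) {
  if (!is.null(st$inputs)) {
    if (!file.exists(st$inputs$points %||% ""))
      stop("anatomy stage: missing input point file")
    pts <- read.csv(st$inputs$points)
  } else if (!is.null(st$simulate)) {
    pts <- do.call(genCellPoints, modifyList(list(seed = seed),
                                             as.list(st$simulate)))
  } else stop("anatomy stage: provide inputs or a simulate stanza")
  sp <- prm$spacing_um
  pad <- 4 * prm$bandwidth_um
  rng <- apply(.asPointMatrix(pts), 2, range)
  dims <- pmax(ceiling((rng[2, ] - rng[1, ] + 2 * pad) / sp), 4)
  mask <- array(TRUE, dims)
  field <- fitDensity(pts, mask, bandwidthUm = prm$bandwidth_um,
                      spacingUm = sp, originUm = rng[1, ] - pad)
  contours <- densityContours(field, prm$contour_levels)
  out <- list(n_cells = field@nPoints,
              total_mass = sum(field@values) * voxelVolume(field),
              peak_density_per_1000um3 = max(field@values) * 1000,
              n_contours = vapply(contours, length, numeric(1)))
  emit("anatomy.json", function(p)
    jsonlite::write_json(out, p, auto_unbox = TRUE, digits = NA))
  out
}

.stageCfos <- function(st, prm, seed, emit) {
  if (!is.null(st$simulate)) {
    sim <- as.list(st$simulate)
    dims <- unlist(sim$dims %||% c(16, 16, 12))
    masks <- .defaultClusterMasks(dims)
    eff <- matrix(unlist(sim$effects %||% c(1.5, 0, -1)), ncol = 1,
                  dimnames = list(names(masks), "bout-like"))
    pairs <- genCfosVolumes(masks, eff, nPerGroup = sim$n_per_group %||% 8,
                            seed = seed)
  } else stop("cfos stage: provide a simulate stanza (file volumes via convertFile)")
  bulk <- t(vapply(pairs, function(pr)
    bulkClusterSignal(normalizeActivity(pr), masks),
    numeric(length(masks))))
  conds <- vapply(pairs, function(pr) pr@condition, character(1))
  em <- conditionEffects(bulk, conds, baseline = prm$baseline,
                        varEqual = prm$var_equal)
  out <- list(d = effectSizes(em), p = pValues(em))
  emit("effects.csv", function(p) write.csv(effectSizes(em), p))
  emit("cfos.json", function(p)
    jsonlite::write_json(list(d = as.data.frame(effectSizes(em))), p,
                         digits = NA))
  out
}

# three disjoint block masks used by the simulated c-fos stage
.defaultClusterMasks <- function(dims) {
  mk <- function(xr, yr) {
    m <- array(FALSE, dims)
    m[xr, yr, ] <- TRUE
    m
  }
  third <- floor(dims[1] / 3)
  list(A = mk(1:third, 1:floor(dims[2] / 2)),
       B = mk((third + 1):(2 * third), 1:floor(dims[2] / 2)),
       C = mk((2 * third + 1):dims[1], 1:floor(dims[2] / 2)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
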