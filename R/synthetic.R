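#' Parameters of the synthetic follower dyad
#'
#' Defaults emulate the juvenile zebrafish kinematics the assay is built
#' around: swim bouts at about 1.25 Hz and an average speed of about
#' 5 mm/s, with a preferred social distance of 10 mm and a short-range
#' exclusion zone.
#'
#' @param gain attraction gain: how strongly a range error (distance to
#'   the partner minus the preferred distance, mm) biases the follower's
#'   heading; expressed as approach speed per mm of error (mm/s per mm).
#' @param preferredMm preferred distance to the partner, mm.
#' @param exclusionMm exclusion radius, mm (must be < `preferredMm`);
#'   inside it the follower turns away.
#' @param boutFreqHz bout frequency, Hz.
#' @param boutSpeedMmS average speed, mm/s (per-bout displacement is
#'   `boutSpeedMmS / boutFreqHz`).
#' @param headingNoiseSd SD of the per-bout heading perturbation, rad.
#' @return A named list of follower parameters.
#' @export
followerParams <- function(gain = 1, preferredMm = 10, exclusionMm = 4,
                           boutFreqHz = 1.25, boutSpeedMmS = 5,
                           headingNoiseSd = 0.6) {
  stopifnot(exclusionMm < preferredMm, boutFreqHz > 0, boutSpeedMmS > 0)
  list(gain = gain, preferredMm = preferredMm, exclusionMm = exclusionMm,
       boutFreqHz = boutFreqHz, boutSpeedMmS = boutSpeedMmS,
       headingNoiseSd = headingNoiseSd)
}

.wrapAngle <- function(a) atan2(sin(a), cos(a))

#' Simulate a shoaling dyad with known coupling
#'
#' Two bout-structured swimmers in a circular dish. Each fish executes
#' discrete bouts (Poisson-timed at the bout frequency) that displace it
#' by `boutSpeed / boutFreq` along its heading; between bouts it holds
#' position. Headings random-walk with per-bout noise. In a `follower`
#' dyad the second fish biases its heading towards the first when
#' farther than the preferred distance (with a weight growing with the
#' attraction gain and the range error) and away from it inside the
#' exclusion radius; an `independent` dyad has zero coupling. Walls are
#' reflective. Deterministic under `seed`.
#'
#' @param kind `"follower"` or `"independent"`.
#' @param params a [followerParams()] list.
#' @param durationS duration, s (>= 600 s, one attraction chunk).
#' @param fps sampling rate, frames per second.
#' @param dishRadiusMm dish radius, mm (100 mm dish = radius 50).
#' @param seed RNG seed.
#' @return list with elements `focal` and `neighbor` ([Track-class]);
#'   for a follower dyad, `neighbor` is the followed fish and `focal`
#'   the follower.
#' @export
genDyad <- function(kind = c("follower", "independent"),
                    params = followerParams(), durationS = 1200,
                    fps = 30, dishRadiusMm = 50, seed = 1) {
  kind <- match.arg(kind)
  if (durationS < 600) stop("duration must cover at least one 5 min chunk, with margin")
  set.seed(seed)
  n <- floor(durationS * fps)
  dt <- 1 / fps
  pBout <- params$boutFreqHz * dt
  jump <- params$boutSpeedMmS / params$boutFreqHz
  pos <- array(0, c(n, 2, 2))  # frame x (x, y) x fish
  pos[1, , 1] <- c(-10, 0)
  pos[1, , 2] <- c(10, 0)
  th <- runif(2, -pi, pi)
  lead <- 2L  # leader wanders; fish 1 is the (possibly coupled) follower
  for (i in 2:n) {
    pos[i, , ] <- pos[i - 1, , ]
    for (fsh in 1:2) {
      if (runif(1) >= pBout) next
      th[fsh] <- th[fsh] + rnorm(1, 0, params$headingNoiseSd)
      if (kind == "follower" && fsh == 1L) {
        rel <- pos[i, , lead] - pos[i, , 1]
        dist <- sqrt(sum(rel^2))
        bearing <- atan2(rel[2], rel[1])
        err <- dist - params$preferredMm
        if (dist < params$exclusionMm) {
          th[1] <- th[1] + 0.8 * .wrapAngle(bearing + pi - th[1])
        } else if (err > 0) {
          w <- min(1, params$gain * err / params$boutSpeedMmS)
          th[1] <- th[1] + w * .wrapAngle(bearing - th[1])
        }
      }
      cand <- pos[i, , fsh] + jump * c(cos(th[fsh]), sin(th[fsh]))
      if (sqrt(sum(cand^2)) > dishRadiusMm - jump) {
        # reflective wall: turn back towards the dish centre
        th[fsh] <- atan2(-pos[i, 2, fsh], -pos[i, 1, fsh]) + rnorm(1, 0, 0.3)
        cand <- pos[i, , fsh] + jump * c(cos(th[fsh]), sin(th[fsh]))
      }
      pos[i, , fsh] <- cand
    }
  }
  t <- (seq_len(n) - 1) * dt
  list(focal = Track(t, pos[, 1, 1], pos[, 2, 1]),
       neighbor = Track(t, pos[, 1, 2], pos[, 2, 2]))
}

#' Parameters of the synthetic calcium-imaging population
#'
#' The population mirrors the composition the juvenile recordings
#' suggest: 13% of neurons tuned to bout-like motion (the reported BPN
#' fraction), the remainder split between untuned responders (equal
#' response to every stimulus) and silent neurons. Traces use the
#' nuclear GCaMP6s kinetics (single-exponential kernel, tau = 7 s),
#' acquisition at 5 volumes/s and fivefold mean downsampling to 1/s.
#'
#' @param nNeurons population size.
#' @param selectiveFrac fraction of frequency-tuned neurons.
#' @param responderFrac fraction of untuned, equally responding neurons
#'   (the rest are silent).
#' @param centreHz population tuning centre of selective neurons, Hz.
#' @param centreLogSd SD of per-neuron tuning centres around `centreHz`
#'   on the log2 axis; the recorded DT population shows a spread of
#'   tuning peaks around its 1.2 Hz mean, and a spread of 0.35 log2
#'   units keeps every selective neuron within the bout-preferring
#'   regime (category response ratio > 3).
#' @param logWidth tuning width on the log2 frequency axis.
#' @param amplitude peak response amplitude, dF/F units.
#' @param tauS calcium kernel time constant, s.
#' @param rateHz acquisition rate, volumes/s.
#' @param downsample downsampling factor applied after acquisition.
#' @param noiseSd trace noise SD in dF/F units (0.25 = 25% of a unit
#'   response amplitude).
#' @param baselineF baseline fluorescence level, a.u.
#' @return A named parameter list.
#' @export
neuronSimParams <- function(nNeurons = 1000, selectiveFrac = 0.13,
                            responderFrac = 0.37, centreHz = 1.2,
                            centreLogSd = 0.35, logWidth = 1,
                            amplitude = 1, tauS = 7,
                            rateHz = 5, downsample = 5, noiseSd = 0.25,
                            baselineF = 100) {
  stopifnot(tauS > 0, rateHz > 0, selectiveFrac + responderFrac <= 1)
  list(nNeurons = nNeurons, selectiveFrac = selectiveFrac,
       responderFrac = responderFrac, centreHz = centreHz,
       centreLogSd = centreLogSd, logWidth = logWidth,
       amplitude = amplitude, tauS = tauS,
       rateHz = rateHz, downsample = downsample, noiseSd = noiseSd,
       baselineF = baselineF)
}

#' Simulate calcium traces with known tuning
#'
#' Selective neurons respond to each stimulus with a log-Gaussian
#' frequency tuning around the tuning centre; untuned responders respond
#' equally to every stimulus; silent neurons never respond. The drive is
#' low-pass filtered with the single-exponential calcium kernel
#' (instantaneous rise, tau decay), converted to fluorescence around the
#' baseline level, corrupted with Gaussian noise at the acquisition
#' rate, and mean-downsampled. Deterministic under `seed`.
#'
#' @param params a [neuronSimParams()] list.
#' @param schedule a [StimulusSchedule-class] covering the five standard
#'   frequencies.
#' @param seed RNG seed.
#' @return list with `traces` (a [TraceSet-class] at
#'   `rateHz/downsample`) and `truth` (data.frame: neuron, class in
#'   selective/responder/silent, centre_hz).
#' @export
genTraces <- function(params = neuronSimParams(),
                      schedule = makeFrequencySchedule(), seed = 1) {
  set.seed(seed)
  tb <- scheduleTable(schedule)
  rate <- params$rateHz
  nT <- ceiling((max(tb$onset_s + tb$duration_s) + 30) * rate)
  nSel <- round(params$nNeurons * params$selectiveFrac)
  nResp <- round(params$nNeurons * params$responderFrac)
  nSil <- params$nNeurons - nSel - nResp
  cls <- c(rep("selective", nSel), rep("responder", nResp),
           rep("silent", nSil))
  centres <- rep(NA_real_, params$nNeurons)
  centres[cls == "selective"] <-
    2^rnorm(nSel, log2(params$centreHz), params$centreLogSd)
  gainFor <- function(freq) {
    g <- numeric(params$nNeurons)
    sel <- cls == "selective"
    g[sel] <- params$amplitude *
      exp(-(log2(freq) - log2(centres[sel]))^2 / (2 * params$logWidth^2))
    g[cls == "responder"] <- params$amplitude * 0.5
    g
  }
  # stimulus drive per neuron x time, then exponential calcium filtering
  drive <- matrix(0, params$nNeurons, nT)
  for (k in seq_len(nrow(tb))) {
    i0 <- round(tb$onset_s[k] * rate) + 1L
    i1 <- min(nT, i0 + round(tb$duration_s[k] * rate) - 1L)
    drive[, i0:i1] <- drive[, i0:i1] + gainFor(tb$freq_hz[k])
  }
  alpha <- (1 / rate) / params$tauS
  dff <- matrix(0, params$nNeurons, nT)
  for (j in 2:nT)
    dff[, j] <- dff[, j - 1] + (drive[, j] - dff[, j - 1]) * alpha
  f <- params$baselineF *
    (1 + dff + matrix(rnorm(length(dff), 0, params$noiseSd),
                      nrow(dff), ncol(dff)))
  f <- pmax(f, 0)
  ts <- TraceSet(f, rateHz = rate)
  ts <- downsampleTraces(ts, params$downsample)
  list(traces = ts,
       truth = data.frame(neuron = rownames(traceMatrix(ts)), class = cls,
                          centre_hz = centres, stringsAsFactors = FALSE))
}

#' Simulate spatially clustered cell coordinates
#'
#' Gaussian point clouds around given cluster centres in reference-brain
#' space (um). Deterministic under `seed`.
#'
#' @param centres matrix (clusters x 3) of cluster centres, um.
#' @param counts cells per cluster.
#' @param sigmaUm isotropic cloud SD, um (0 = all points at the centre).
#' @param seed RNG seed.
#' @return data.frame with columns x_um, y_um, z_um, cluster.
#' @export
genCellPoints <- function(centres, counts, sigmaUm = 15, seed = 1) {
  set.seed(seed)
  centres <- matrix(as.numeric(as.matrix(centres)), ncol = 3)
  stopifnot(nrow(centres) == length(counts))
  out <- lapply(seq_len(nrow(centres)), function(k) {
    n <- counts[k]
    data.frame(x_um = rnorm(n, centres[k, 1], sigmaUm),
               y_um = rnorm(n, centres[k, 2], sigmaUm),
               z_um = rnorm(n, centres[k, 3], sigmaUm),
               cluster = k)
  })
  do.call(rbind, out)
}

#' Simulate two-channel volumes with planted effect sizes
#'
#' For each animal, the reference channel is a smooth base intensity
#' attenuated exponentially with depth (`exp(-z / lambda)`); the
#' activity channel is the reference scaled, inside each cluster mask,
#' by an animal-level factor drawn so that the condition group differs
#' from baseline by the requested Cohen's d (group mean
#' `1 + d * animalSd`, SD `animalSd`), plus voxel noise. Deterministic
#' under `seed`.
#'
#' @param masks named list of disjoint logical 3-D arrays.
#' @param effects cluster x condition matrix of planted Cohen's d values
#'   (rownames = cluster names, colnames = non-baseline conditions).
#' @param nPerGroup animals per condition group.
#' @param baseline baseline condition label.
#' @param baseIntensity mean reference intensity, a.u.
#' @param lambdaUm depth-attenuation constant, um.
#' @param spacingUm voxel spacing, um.
#' @param animalSd between-animal SD of the cluster activity factor.
#' @param voxelNoiseSd voxel noise SD relative to local intensity.
#' @param seed RNG seed.
#' @return list of [VolumePair-class] objects (baseline group first).
#' @export
genCfosVolumes <- function(masks, effects, nPerGroup = 8,
                           baseline = "no-stimulus", baseIntensity = 100,
                           lambdaUm = 200, spacingUm = 4,
                           animalSd = 0.1, voxelNoiseSd = 0.02, seed = 1) {
  set.seed(seed)
  stopifnot(is.matrix(effects), !is.null(rownames(effects)),
            !is.null(colnames(effects)),
            all(rownames(effects) %in% names(masks)))
  dims <- dim(masks[[1]])
  z <- (seq_len(dims[3]) - 1) * spacingUm
  atten <- exp(-z / lambdaUm)
  depth <- array(rep(atten, each = dims[1] * dims[2]), dims)
  conditions <- c(baseline, colnames(effects))
  out <- list()
  for (cn in conditions) {
    for (a in seq_len(nPerGroup)) {
      ref <- baseIntensity * depth *
        (1 + voxelNoiseSd * array(rnorm(prod(dims)), dims))
      act <- ref
      for (cl in rownames(effects)) {
        dTarget <- if (cn == baseline) 0 else effects[cl, cn]
        fac <- rnorm(1, 1 + dTarget * animalSd, animalSd)
        act[masks[[cl]]] <- act[masks[[cl]]] * fac
      }
      act <- act * (1 + voxelNoiseSd * array(rnorm(prod(dims)), dims))
      out[[length(out) + 1L]] <- new("VolumePair",
        activity = pmax(act, 0), reference = pmax(ref, 0),
        animal = sprintf("%s_%02d", cn, a), condition = cn)
    }
  }
  out
}
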