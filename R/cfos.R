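.gauss3dSmooth <- function(vol, sigmaVox) {
  # separable Gaussian smoothing along each axis
  for (a in 1:3) {
    s <- sigmaVox[a]
    if (s <= 0) next
    half <- ceiling(3 * s)
    k <- dnorm(-half:half, sd = s)
    k <- k / sum(k)
    vol <- apply(vol, setdiff(1:3, a), function(v) {
      n <- length(v)
      vp <- c(rep(v[1], half), v, rep(v[n], half))
      convolve(vp, rev(k), type = "filter")
    })
    vol <- aperm(vol, order(c(a, setdiff(1:3, a))))
  }
  vol
}

#' Depth-normalized activity volume
#'
#' Divides the activity (c-fos) channel voxel-wise by the reference
#' (elavl3) channel, cancelling the drop of signal intensity with tissue
#' depth. Voxels whose reference intensity falls below `floorFrac` of
#' the in-brain median reference are masked out (NA) and excluded from
#' downstream means. For quantification the unfiltered reference is used
#' (default); `smoothSigmaUm` applies a 3-D Gaussian to the reference
#' first, a display-oriented option.
#'
#' @param pair a [VolumePair-class].
#' @param smoothSigmaUm optional length-3 Gaussian sigma for the
#'   reference channel, um (NULL = off).
#' @param spacingUm voxel spacing, um, used only with `smoothSigmaUm`.
#' @param floorFrac reference floor as a fraction of the in-brain median.
#' @param brainMask optional logical array restricting the median to the
#'   brain; default uses all positive-reference voxels.
#' @return 3-D array of normalized activity, NA on masked voxels.
#' @export
normalizeActivity <- function(pair, smoothSigmaUm = NULL,
                              spacingUm = c(1, 1, 1), floorFrac = 0.01,
                              brainMask = NULL) {
  stopifnot(is(pair, "VolumePair"))
  ref <- pair@reference
  if (max(ref) == 0) stop("reference channel is all zero")
  if (!is.null(smoothSigmaUm))
    ref <- .gauss3dSmooth(ref, smoothSigmaUm / rep(spacingUm, length.out = 3))
  med <- if (is.null(brainMask)) median(ref[ref > 0]) else median(ref[brainMask])
  out <- pair@activity / ref
  out[ref < floorFrac * med] <- NA_real_
  out
}

#' Bulk normalized signal per activity cluster
#'
#' Average normalized activity over all (unmasked) voxels of each
#' cluster mask, one value per cluster per animal.
#'
#' @param normVol normalized activity volume from [normalizeActivity()].
#' @param masks named list of logical 3-D arrays, one per cluster.
#' @return Named numeric vector of per-cluster means; a cluster whose
#'   voxels are all masked yields NA with a warning.
#' @export
bulkClusterSignal <- function(normVol, masks) {
  stopifnot(is.list(masks), length(masks) > 0)
  res <- vapply(masks, function(m) {
    v <- normVol[m]
    v <- v[!is.na(v)]
    if (!length(v)) return(NA_real_)
    mean(v)
  }, numeric(1))
  if (anyNA(res))
    warning("fully masked cluster(s): ",
            paste(names(res)[is.na(res)], collapse = ", "))
  res
}

#' Cohen's d with pooled standard deviation
#'
#' `(mean(x) - mean(y)) / s_pooled`, with the pooled SD weighting the
#' group variances by their degrees of freedom.
#'
#' @param x,y numeric samples.
#' @return Cohen's d (NA when the pooled SD is zero).
#' @examples
#' cohensD(c(1, 2, 3), c(0, 1, 2))  # 1
#' @export
cohensD <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp <- sqrt(((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2))
  if (!is.finite(sp) || sp == 0) return(NA_real_)
  (mean(x) - mean(y)) / sp
}

#' Condition effect sizes per activity cluster
#'
#' For every cluster and every non-baseline condition: Cohen's d of the
#' bulk normalized signal against the no-stimulus baseline (negative d =
#' signal below baseline) and a two-tailed two-sample t-test. Tests are
#' Bonferroni-corrected within each cluster's family of comparisons:
#' significance tiers at p < 0.05/3, 0.01/3 and 0.001/3 for the standard
#' three stimulus conditions.
#'
#' @param bulk animal x cluster matrix of bulk normalized signal.
#' @param conditions condition label per animal (row of `bulk`).
#' @param baseline baseline condition label.
#' @param varEqual use the equal-variance Student t-test (default);
#'   FALSE switches to Welch.
#' @return An [EffectMatrix-class].
#' @export
conditionEffects <- function(bulk, conditions, baseline = "no-stimulus",
                             varEqual = TRUE) {
  bulk <- as.matrix(bulk)
  conditions <- as.character(conditions)
  stopifnot(length(conditions) == nrow(bulk))
  if (!baseline %in% conditions) stop("baseline condition absent")
  conds <- setdiff(unique(conditions), baseline)
  nFam <- length(conds)
  if (any(table(conditions) < 2)) stop("need at least 2 animals per group")
  base <- bulk[conditions == baseline, , drop = FALSE]
  d <- p <- matrix(NA_real_, ncol(bulk), nFam,
                   dimnames = list(colnames(bulk), conds))
  for (cn in conds) {
    grp <- bulk[conditions == cn, , drop = FALSE]
    for (j in seq_len(ncol(bulk))) {
      x <- grp[, j]; y <- base[, j]
      x <- x[!is.na(x)]; y <- y[!is.na(y)]
      if (length(x) < 2 || length(y) < 2) next
      d[j, cn] <- cohensD(x, y)
      if (!is.na(d[j, cn]))
        p[j, cn] <- t.test(x, y, var.equal = varEqual)$p.value
    }
  }
  tier <- matrix("", nrow(d), ncol(d), dimnames = dimnames(d))
  tier[!is.na(p) & p < 0.05 / nFam] <- "*"
  tier[!is.na(p) & p < 0.01 / nFam] <- "**"
  tier[!is.na(p) & p < 0.001 / nFam] <- "***"
  ns <- table(conditions)
  new("EffectMatrix", d = d, p = p, tier = tier, baseline = baseline,
      nPerGroup = setNames(as.integer(ns), names(ns)))
}

#' Hierarchical clustering of effect-size profiles
#'
#' Agglomerative clustering (average linkage, Euclidean metric) of the
#' rows of an effect matrix. Rows containing undefined effect sizes are
#' excluded and reported, not imputed.
#'
#' @param effects an [EffectMatrix-class] (or a plain numeric matrix).
#' @return list with `hclust` (the [stats::hclust] tree), `order`
#'   (leaf order), `labels`, `newick` (the tree in Newick notation) and
#'   `dropped` (labels of excluded rows).
#' @export
effectDendrogram <- function(effects) {
  d <- if (is(effects, "EffectMatrix")) effectSizes(effects) else as.matrix(effects)
  if (is.null(rownames(d))) rownames(d) <- paste0("cluster", seq_len(nrow(d)))
  ok <- rowSums(is.na(d)) == 0
  dropped <- rownames(d)[!ok]
  d <- d[ok, , drop = FALSE]
  if (nrow(d) < 1) stop("no complete rows to cluster")
  if (nrow(d) == 1) {
    return(list(hclust = NULL, order = 1L, labels = rownames(d),
                newick = paste0("(", rownames(d), ");"), dropped = dropped))
  }
  hc <- hclust(dist(d), method = "average")
  list(hclust = hc, order = hc$order, labels = rownames(d)[hc$order],
       newick = ape::write.tree(ape::as.phylo(hc)), dropped = dropped)
}
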