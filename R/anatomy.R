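.asPointMatrix <- function(points) {
  if (is.data.frame(points)) {
    cols <- intersect(c("x_um", "y_um", "z_um"), names(points))
    if (length(cols) == 3) points <- points[, cols] else points <- points[, 1:3]
  }
  m <- as.matrix(points)
  storage.mode(m) <- "double"
  colnames(m) <- c("x", "y", "z")
  m
}

.gridCenters <- function(dims, spacing, origin)
  lapply(1:3, function(a) origin[a] + (seq_len(dims[a]) - 1) * spacing[a])

#' Per-hemisphere Gaussian kernel density of cell coordinates
#'
#' Fits an isotropic Gaussian KDE to cell coordinates in reference-brain
#' space, one kernel per hemisphere (split at the mediolateral midline;
#' points exactly on the midline count as left). Each hemisphere's field
#' is evaluated on that hemisphere's voxels only, the two fields are
#' merged, masked to the brain, and rescaled so that the density
#' integrated over the masked grid equals the total cell count. Density
#' values are per cubic micrometre.
#'
#' @param points cell coordinates: matrix or data.frame with columns
#'   x_um, y_um, z_um.
#' @param mask logical 3-D array, TRUE inside the brain; defines the
#'   evaluation grid.
#' @param bandwidthUm Gaussian kernel bandwidth, um (10 for juveniles,
#'   14 for 7 d.p.f. larvae).
#' @param spacingUm voxel spacing, um (scalar or length 3).
#' @param originUm coordinate of the centre of voxel (1,1,1), um.
#' @param midlineUm mediolateral (x) coordinate of the midline, um.
#' @return A [DensityField-class].
#' @export
fitDensity <- function(points, mask, bandwidthUm = 10, spacingUm = 2,
                       originUm = c(0, 0, 0),
                       midlineUm = NULL) {
  stopifnot(bandwidthUm > 0, is.array(mask), length(dim(mask)) == 3)
  spacingUm <- rep(spacingUm, length.out = 3)
  p <- .asPointMatrix(points)
  dims <- dim(mask)
  ctr <- .gridCenters(dims, spacingUm, originUm)
  if (is.null(midlineUm)) midlineUm <- mean(range(ctr[[1]]))
  field <- array(0, dims)
  n <- nrow(p)
  if (n == 0) {
    warning("empty point set: returning a zero density field")
    return(new("DensityField", values = field, spacing = spacingUm,
               origin = originUm, mask = mask, nPoints = 0))
  }
  leftPt <- p[, "x"] <= midlineUm
  leftVox <- ctr[[1]] <= midlineUm
  h <- bandwidthUm
  for (side in c(TRUE, FALSE)) {
    sel <- which(leftPt == side)
    if (!length(sel)) next
    xi <- which(leftVox == side)
    if (!length(xi)) next
    sub <- array(0, c(length(xi), dims[2], dims[3]))
    for (i in sel) {
      gx <- dnorm(ctr[[1]][xi], p[i, "x"], h)
      gy <- dnorm(ctr[[2]], p[i, "y"], h)
      gz <- dnorm(ctr[[3]], p[i, "z"], h)
      sub <- sub + outer(outer(gx, gy), gz)
    }
    field[xi, , ] <- sub
  }
  field[!mask] <- 0
  tot <- sum(field) * prod(spacingUm)
  if (tot <= 0) {
    warning("all density mass falls outside the brain mask")
    return(new("DensityField", values = field, spacing = spacingUm,
               origin = originUm, mask = mask, nPoints = n))
  }
  field <- field * n / tot
  new("DensityField", values = field, spacing = spacingUm,
      origin = originUm, mask = mask, nPoints = n)
}

#' Iso-density contours of a density field projection
#'
#' Binarizes the field at each threshold (given in cells per 1000 um^3),
#' computes a 2-D maximum-intensity projection along the requested
#' anatomical axis and extracts closed contours of the binarized
#' projection (marching squares at level 0.5).
#'
#' @param field a [DensityField-class].
#' @param thresholdsPer1000um3 density thresholds, cells per 1000 um^3
#'   (defaults 0.1, 0.15, 0.3).
#' @param axis projection axis (1 = x, 2 = y, 3 = z; default dorsal view).
#' @return Named list (one element per threshold) of lists of contour
#'   polygons, each a data.frame with the two in-plane coordinates (um).
#' @export
densityContours <- function(field, thresholdsPer1000um3 = c(0.1, 0.15, 0.3),
                            axis = 3) {
  stopifnot(is(field, "DensityField"), all(thresholdsPer1000um3 > 0))
  keep <- setdiff(1:3, axis)
  ctr <- .gridCenters(dim(field@values), field@spacing, field@origin)
  out <- lapply(thresholdsPer1000um3, function(thr) {
    bin <- field@values > thr / 1000
    proj <- apply(bin, keep, max)
    if (!any(proj == 1)) return(list())
    cl <- grDevices::contourLines(ctr[[keep[1]]], ctr[[keep[2]]],
                                  proj * 1, levels = 0.5)
    lapply(cl, function(cc) {
      d <- data.frame(cc$x, cc$y)
      names(d) <- paste0(c("x", "y", "z")[keep], "_um")
      d
    })
  })
  names(out) <- sprintf("%g_per_1000um3", thresholdsPer1000um3)
  out
}

#' Fraction of cells per anatomical region
#'
#' Assigns each cell to the region label of its nearest voxel in a label
#' volume and returns the fraction of cells per region. Cells outside
#' the volume, or on voxels carrying no label (0), are counted as
#' `unassigned`; all fractions including `unassigned` sum to 1.
#'
#' @param points cell coordinates (columns x_um, y_um, z_um).
#' @param labels integer 3-D array of region labels (0 = no region).
#' @param regionNames character vector naming labels 1..max.
#' @param spacingUm,originUm grid geometry as in [fitDensity()].
#' @return Named numeric vector of fractions (regions + `unassigned`).
#' @export
regionFractions <- function(points, labels, regionNames,
                            spacingUm = 2, originUm = c(0, 0, 0)) {
  spacingUm <- rep(spacingUm, length.out = 3)
  p <- .asPointMatrix(points)
  dims <- dim(labels)
  idx <- sapply(1:3, function(a)
    round((p[, a] - originUm[a]) / spacingUm[a]) + 1)
  idx <- matrix(idx, ncol = 3)
  inside <- idx[, 1] >= 1 & idx[, 1] <= dims[1] &
    idx[, 2] >= 1 & idx[, 2] <= dims[2] &
    idx[, 3] >= 1 & idx[, 3] <= dims[3]
  lab <- rep(0L, nrow(p))
  if (any(inside)) lab[inside] <- labels[idx[inside, , drop = FALSE]]
  counts <- vapply(seq_along(regionNames), function(k) sum(lab == k),
                   numeric(1))
  res <- c(counts, sum(lab == 0)) / nrow(p)
  names(res) <- c(regionNames, "unassigned")
  res
}
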