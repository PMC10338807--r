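## CT preprocessing: nearest-neighbour resampling to a common voxel grid
## (0.68 x 0.68 x 1.75 mm), HU windowing to [-1200, 600] rescaled to
## [0, 1], and extraction of paired cubic nodule/mask regions centred on
## the consensus of the readers' nodule centres.

#' A CT volume with voxel-spacing metadata
#'
#' @param intensities 3-d numeric array (Hounsfield units before
#'   normalisation).
#' @param spacing (x, y, z) mm per voxel, strictly positive.
#' @param origin mm triple (carried through, not used by the crop).
#' @return `msnet_ct_volume` object.
#' @export
ct_volume <- function(intensities, spacing, origin = c(0, 0, 0)) {
  if (length(dim(intensities)) != 3L) stopf("ct_volume: array rank must be 3")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stopf("ct_volume: spacing must be three positive numbers")
  structure(list(intensities = intensities, spacing = spacing,
                 origin = as.numeric(origin)),
            class = "msnet_ct_volume")
}

#' Nearest-neighbour resampling to a target spacing
#'
#' The output grid has `round(size * spacing / target)` voxels per axis;
#' each output voxel takes the value of the nearest input voxel (so the
#' output value multiset is a subset of the input values, and masks stay
#' binary).
#'
#' @param vol a [ct_volume()].
#' @param target_spacing mm triple, default `c(0.68, 0.68, 1.75)`.
#' @return Resampled [ct_volume()].
#' @export
resample_nearest <- function(vol, target_spacing = c(0.68, 0.68, 1.75)) {
  stopifnot(inherits(vol, "msnet_ct_volume"))
  tgt <- as.numeric(target_spacing)
  if (any(!is.finite(tgt)) || any(tgt <= 0))
    stopf("resample_nearest: target spacing must be positive")
  d <- dim(vol$intensities)
  if (all(abs(vol$spacing - tgt) < 1e-12)) return(vol)
  nd <- pmax(1L, as.integer(round(d * vol$spacing / tgt)))
  idx <- lapply(1:3, function(a) {
    centers <- (seq_len(nd[a]) - 0.5) * tgt[a]        # mm position
    clip(round_half_up(centers / vol$spacing[a] + 0.5), 1L, d[a])
  })
  ct_volume(vol$intensities[idx[[1]], idx[[2]], idx[[3]], drop = FALSE],
            tgt, vol$origin)
}

#' Window to a Hounsfield range and rescale to \[0, 1\]
#'
#' Values are clipped to `[lo, hi]` and linearly mapped so that `lo` is 0
#' and `hi` is 1.
#'
#' @param vol a [ct_volume()].
#' @param lo,hi window bounds in HU; defaults -1200 and 600.
#' @return [ct_volume()] with intensities in \[0, 1\].
#' @export
window_normalize <- function(vol, lo = -1200, hi = 600) {
  stopifnot(inherits(vol, "msnet_ct_volume"))
  if (lo >= hi) stopf("window_normalize: lo must be below hi")
  out <- vol
  out$intensities <- clip((vol$intensities - lo) / (hi - lo), 0, 1)
  out
}

#' Consensus nodule centre
#'
#' Component-wise arithmetic mean of the readers' centres, rounded half-up
#' to an integer voxel.
#'
#' @param centers non-empty list of voxel triples (or a matrix with one
#'   row per reader).
#' @return Integer voxel triple.
#' @export
consensus_center <- function(centers) {
  if (is.list(centers)) {
    if (!length(centers)) stopf("consensus_center: empty centre list")
    centers <- do.call(rbind, centers)
  }
  if (is.null(dim(centers))) centers <- matrix(centers, nrow = 1L)
  if (!nrow(centers)) stopf("consensus_center: empty centre list")
  as.integer(round_half_up(colMeans(centers)))
}

cube_index_range <- function(center, side) {
  start <- center - side %/% 2L
  list(start = start, end = start + side - 1L)
}

#' Extract a cubic region around a centre, zero-padding outside the volume
#'
#' The cube's centre voxel (position `side/2 + 1` on each axis) equals the
#' volume value at `center`. Regions falling outside the volume are filled
#' with 0 (normalised air).
#'
#' @param vol a (resampled, normalised) [ct_volume()] or a plain 3-d array.
#' @param center integer voxel triple, inside the volume.
#' @param side cube side in voxels (default 80).
#' @return `side^3` numeric array.
#' @export
extract_cube <- function(vol, center, side = 80L) {
  arr <- if (inherits(vol, "msnet_ct_volume")) vol$intensities else vol
  d <- dim(arr)
  center <- as.integer(round_half_up(center))
  if (any(center < 1L) || any(center > d))
    stopf("extract_cube: center (%s) outside the volume (%s)",
          paste(center, collapse = ","), paste(d, collapse = "x"))
  rg <- cube_index_range(center, as.integer(side))
  out <- array(0, rep(as.integer(side), 3L))
  src <- dst <- vector("list", 3L)
  for (a in 1:3) {
    s1 <- max(rg$start[a], 1L); s2 <- min(rg$end[a], d[a])
    src[[a]] <- s1:s2
    dst[[a]] <- (s1 - rg$start[a] + 1L):(s2 - rg$start[a] + 1L)
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- arr[src[[1]], src[[2]], src[[3]]]
  out
}

#' Crop one reader's mask with the same geometry as the nodule cube
#'
#' Uses the consensus centre so nodule cube and mask cube are
#' voxel-aligned; the mask is the specific reader's own segmentation.
#'
#' @param annotation a [reader_annotation()] whose mask is on the same
#'   (resampled) grid as the volume.
#' @param center consensus centre voxel triple.
#' @param side cube side in voxels.
#' @return Binary `side^3` array.
#' @export
build_mask_cube <- function(annotation, center, side = 80L) {
  mask <- annotation$mask
  if (is.null(mask)) stopf("annotation has no mask")
  if (!is_binary_array(mask)) stopf("mask is not strictly binary")
  out <- extract_cube(mask * 1, center, side)
  out
}

#' Paired nodule/mask cubes
#'
#' @param nodule_cube normalised intensity cube in \[0, 1\].
#' @param mask_cube binary cube of identical dims.
#' @return `msnet_roi_pair` object.
#' @export
roi_pair <- function(nodule_cube, mask_cube) {
  if (!identical(dim(nodule_cube), dim(mask_cube)))
    stopf("roi_pair: cube shapes differ")
  if (min(nodule_cube) < 0 || max(nodule_cube) > 1)
    stopf("roi_pair: nodule cube values outside [0, 1]")
  if (!is_binary_array(mask_cube)) stopf("roi_pair: mask not binary")
  structure(list(nodule = nodule_cube, mask = mask_cube * 1),
            class = "msnet_roi_pair")
}

#' Preprocess one nodule record into per-reader ROI pairs
#'
#' Resamples the volume and every reader mask with nearest neighbour,
#' windows/normalises intensities, maps the readers' centres to the
#' resampled grid, takes the consensus centre, and extracts one nodule
#' cube (shared) plus one mask cube per reader.
#'
#' @param vol the scan as a [ct_volume()] (HU intensities).
#' @param record one nodule record from [group_to_nodules()].
#' @param side cube side in voxels.
#' @param target_spacing,lo,hi resampling/windowing parameters.
#' @return List of [roi_pair()] objects, one per reader annotation, with
#'   the source annotation attached as attribute `"annotation"`.
#' @export
preprocess_record <- function(vol, record, side = 80L,
                              target_spacing = c(0.68, 0.68, 1.75),
                              lo = -1200, hi = 600) {
  rs <- resample_nearest(vol, target_spacing)
  rsn <- window_normalize(rs, lo, hi)
  map_center <- function(cv)
    clip(round_half_up((cv - 0.5) * vol$spacing / target_spacing + 0.5),
         1, dim(rs$intensities))
  centers <- lapply(record$annotations, function(a) map_center(a$center))
  ctr <- consensus_center(centers)
  cube <- extract_cube(rsn, ctr, side)
  lapply(record$annotations, function(a) {
    mvol <- ct_volume(a$mask * 1, vol$spacing)
    mres <- resample_nearest(mvol, target_spacing)
    a2 <- a
    a2$mask <- mres$intensities
    pair <- roi_pair(cube, build_mask_cube(a2, ctr, side))
    attr(pair, "annotation") <- a
    pair
  })
}
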