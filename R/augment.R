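## Online training-time augmentation: integer translation (step 0-5 voxels
## per axis), axis permutation followed by an in-plane rotation of
## 45/135/225 degrees, and independent per-axis flips. Cube and mask
## always receive the identical geometric transform; intensities are
## interpolated linearly, masks with nearest neighbour so they stay
## binary. Class rebalancing replicates malignant samples (which then draw
## fresh augmentations) until the class counts match.

#' Augmentation configuration
#'
#' @param max_translate maximum per-axis translation step in voxels.
#' @param rotation_angles allowed in-plane rotation angles (degrees).
#' @param p_apply default probability that each augmentation is applied to
#'   a sample.
#' @param p_translate,p_rotate,p_flip per-operation overrides of
#'   `p_apply` (e.g. the reduced training profile disables rotation, whose
#'   interpolation smears voxel-scale structures at small cube sides).
#' @return Configuration list.
#' @export
msnet_augment_config <- function(max_translate = 5L,
                                 rotation_angles = c(45, 135, 225),
                                 p_apply = 0.5, p_translate = p_apply,
                                 p_rotate = p_apply, p_flip = p_apply) {
  if (max_translate < 0 || max_translate > 5)
    stopf("max_translate must lie in [0, 5]")
  if (!all(rotation_angles %in% c(45, 135, 225)))
    stopf("rotation angles must be a subset of {45, 135, 225}")
  list(max_translate = as.integer(max_translate),
       rotation_angles = rotation_angles, p_apply = p_apply,
       p_translate = p_translate, p_rotate = p_rotate, p_flip = p_flip)
}

#' Random integer translation of a cube/mask pair
#'
#' Per-axis step drawn uniformly from 0..`max_step`, direction drawn
#' separately; both cubes are shifted by the same vector with zero fill.
#'
#' @param pair an [roi_pair()].
#' @param max_step maximum step (default 5).
#' @return Translated [roi_pair()].
#' @export
random_translate <- function(pair, max_step = 5L) {
  step <- sample(0:max_step, 3L, replace = TRUE) *
    sample(c(-1L, 1L), 3L, replace = TRUE)
  roi_pair(shift3d(pair$nodule, step), shift3d(pair$mask, step))
}

## In-plane rotation of every (1,2)-plane slice about the cube centre.
rotate_slices <- function(arr, angle_deg, interp = c("linear", "nearest")) {
  interp <- match.arg(interp)
  d <- dim(arr)
  n1 <- d[1]; n2 <- d[2]
  th <- angle_deg * pi / 180
  c1 <- (n1 + 1) / 2; c2 <- (n2 + 1) / 2
  io <- rep(seq_len(n1), times = n2) - c1
  jo <- rep(seq_len(n2), each = n1) - c2
  xs <- cos(th) * io + sin(th) * jo + c1   # inverse rotation
  ys <- -sin(th) * io + cos(th) * jo + c2
  out <- array(0, d)
  if (interp == "nearest") {
    xi <- round_half_up(xs); yi <- round_half_up(ys)
    ok <- xi >= 1 & xi <= n1 & yi >= 1 & yi <= n2
    lin <- xi + (yi - 1) * n1
    for (z in seq_len(d[3])) {
      sl <- arr[, , z]
      o <- numeric(n1 * n2)
      o[ok] <- sl[lin[ok]]
      out[, , z] <- o
    }
  } else {
    x0 <- floor(xs); y0 <- floor(ys)
    wx <- xs - x0; wy <- ys - y0
    gather <- function(sl, xi, yi) {
      ok <- xi >= 1 & xi <= n1 & yi >= 1 & yi <= n2
      v <- numeric(length(xi))
      v[ok] <- sl[xi[ok] + (yi[ok] - 1) * n1]
      v
    }
    for (z in seq_len(d[3])) {
      sl <- arr[, , z]
      v00 <- gather(sl, x0, y0); v10 <- gather(sl, x0 + 1, y0)
      v01 <- gather(sl, x0, y0 + 1); v11 <- gather(sl, x0 + 1, y0 + 1)
      out[, , z] <- (1 - wx) * (1 - wy) * v00 + wx * (1 - wy) * v10 +
        (1 - wx) * wy * v01 + wx * wy * v11
    }
  }
  out
}

#' Random 3-d rotation of a cube/mask pair
#'
#' Applies a random permutation of the three axes followed by an in-plane
#' rotation drawn from the configured angle set, about the cube centre.
#'
#' @param pair an [roi_pair()].
#' @param angles candidate angles in degrees.
#' @return Rotated [roi_pair()].
#' @export
random_rotate <- function(pair, angles = c(45, 135, 225)) {
  perm <- sample(3L)
  ang <- angles[[sample.int(length(angles), 1L)]]
  nod <- aperm(pair$nodule, perm)
  msk <- aperm(pair$mask, perm)
  roi_pair(clip(rotate_slices(nod, ang, "linear"), 0, 1),
           rotate_slices(msk, ang, "nearest"))
}

#' Random per-axis flips of a cube/mask pair
#'
#' Each of the three axes is independently reversed with probability 0.5;
#' cube and mask are flipped identically.
#'
#' @param pair an [roi_pair()].
#' @return Flipped [roi_pair()].
#' @export
random_flip <- function(pair) {
  d <- dim(pair$nodule)
  idx <- lapply(1:3, function(a)
    if (runif(1) < 0.5) rev(seq_len(d[a])) else seq_len(d[a]))
  roi_pair(pair$nodule[idx[[1]], idx[[2]], idx[[3]]],
           pair$mask[idx[[1]], idx[[2]], idx[[3]]])
}

#' Apply the augmentation pipeline to one pair
#'
#' Each augmentation (translate, rotate, flip) is applied independently
#' with probability `cfg$p_apply`.
#'
#' @param pair an [roi_pair()].
#' @param cfg an [msnet_augment_config()].
#' @return Augmented [roi_pair()].
#' @export
augment_pair <- function(pair, cfg = msnet_augment_config()) {
  if (runif(1) < cfg$p_translate) pair <- random_translate(pair,
                                                           cfg$max_translate)
  if (runif(1) < cfg$p_rotate) pair <- random_rotate(pair,
                                                     cfg$rotation_angles)
  if (runif(1) < cfg$p_flip) pair <- random_flip(pair)
  pair
}

#' Rebalance a sample list by replicating the malignant class
#'
#' Malignant samples are replicated (round-robin) until the two class
#' counts are equal within one; benign samples appear once. Replicates are
#' marked so the training loop draws fresh augmentations for them.
#'
#' @param samples list of samples each carrying the balancing label.
#' @param key label field used for balancing, `"individual"` (default,
#'   each annotation is a case) or `"panel"`.
#' @return Rebalanced sample list.
#' @export
rebalance <- function(samples, key = "individual") {
  if (!length(samples)) return(samples)
  lab <- vapply(samples, function(s) as.integer(s[[key]]), integer(1))
  n_mal <- sum(lab == 1L); n_ben <- sum(lab == 0L)
  if (n_mal == 0L || n_mal >= n_ben) return(samples)
  mal_idx <- which(lab == 1L)
  extra <- rep(mal_idx, length.out = n_ben - n_mal)
  c(samples, lapply(samples[extra], function(s) {
    s$replicated <- TRUE
    s
  }))
}
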