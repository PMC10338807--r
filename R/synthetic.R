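## Synthetic 3D nodule phantoms with simulated readers. Each phantom is an
## ellipsoid on smoothed background noise, optionally decorated with
## radial spikes (spiculation), surface lobes (lobulation), a bright
## calcification core and Gaussian margin blur. The latent malignancy on
## the 1-5 scale increases monotonically with spike amplitude and lobe
## count; R readers perturb the true mask morphologically and rate
## malignancy/semantic features with ordinal noise, reproducing the
## multi-reader disagreement structure the network is trained on.

#' Phantom generator configuration
#'
#' @param n_nodules number of phantoms.
#' @param readers readers per nodule (default 4).
#' @param cube_side cube side in voxels (80, or 32 for micro-runs).
#' @param malignant_fraction target malignant share; the realised
#'   fraction is exact to rounding.
#' @param rating_noise_sd sd of the Gaussian noise on the latent
#'   malignancy before rounding to each reader's 1-5 rating; 0 gives
#'   noise-free readers (semantic ratings are then also exact).
#' @param mask_jitter maximum morphological perturbation radius (voxels)
#'   of reader masks; a Dice >= 0.7 against the true mask is enforced.
#' @param seed integer RNG seed; all outputs are reproducible from
#'   (config, seed).
#' @return Configuration list.
#' @export
phantom_config <- function(n_nodules = 100L, readers = 4L, cube_side = 80L,
                           malignant_fraction = 0.36,
                           rating_noise_sd = 0.7, mask_jitter = 1L,
                           seed = 1L) {
  if (readers < 1L) stopf("phantom_config: readers must be >= 1")
  if (cube_side < 16L) stopf("phantom_config: cube_side must be >= 16")
  if (malignant_fraction <= 0 || malignant_fraction >= 1)
    stopf("phantom_config: malignant_fraction must lie in (0, 1)")
  list(n_nodules = as.integer(n_nodules), readers = as.integer(readers),
       cube_side = as.integer(cube_side),
       malignant_fraction = malignant_fraction,
       rating_noise_sd = rating_noise_sd,
       mask_jitter = as.integer(mask_jitter), seed = as.integer(seed))
}

nodule_seed <- function(cfg, index, salt = 0L) {
  as.integer((abs(cfg$seed) %% 100003L) * 20011 + index * 7919 +
               salt * 104729) %% 2147483562L
}

#' Latent malignancy score of a phantom shape
#'
#' The documented monotone link between shape and malignancy:
#' `clip(1.5 + 5.5 * spike_amplitude + 0.5 * lobe_count, 1, 5)`.
#' Smooth phantoms (amplitude < 0.1, no lobes) stay in the benign band
#' (< 3); spiky, lobed ones land above 3.5.
#'
#' @param spike_amplitude relative radial spike amplitude (0 = smooth).
#' @param lobe_count number of surface lobes.
#' @return Latent score on the 1-5 scale.
#' @export
latent_malignancy_score <- function(spike_amplitude, lobe_count) {
  clip(1.5 + 5.5 * spike_amplitude + 0.5 * lobe_count, 1, 5)
}

## True semantic scores from the shape parameters (monotone maps).
true_semantic_scores <- function(sh) {
  contrast <- sh$base_intensity - 0.3
  list(
    subtlety = clip(round_half_up(1 + 10 * contrast), 1, 5),
    internalStructure = 1,
    calcification = if (sh$calc_core) 4 else 6,
    sphericity = clip(round_half_up(1 + 4 * min(sh$radii) / max(sh$radii)),
                      1, 5),
    margin = clip(round_half_up(5 - 1.8 * (sh$margin_sigma - 0.4)), 1, 5),
    lobulation = clip(round_half_up(1 + 1.3 * sh$lobe_count), 1, 5),
    spiculation = clip(round_half_up(1 + 8 * sh$spike_amplitude), 1, 5),
    texture = c(1, 3, 5)[sh$texture_type]
  )
}

#' Generate one phantom cube and its ground truth
#'
#' Deterministic in (config, index): the phantom at a given index is
#' always the same. The first `round(malignant_fraction * n_nodules)`
#' indices carry malignant shapes, so the realised class fraction is
#' exact.
#'
#' @param cfg a [phantom_config()].
#' @param index nodule index in `1..n_nodules`.
#' @return List with `cube` (values in \[0, 1\]), `truth` (shape
#'   parameters, latent malignancy, true semantic scores, `true_mask`,
#'   `center`).
#' @export
generate_truth <- function(cfg, index) {
  set.seed(nodule_seed(cfg, index))
  s <- cfg$cube_side
  malignant <- index <= round(cfg$malignant_fraction * cfg$n_nodules)
  radii <- runif(3, 0.14, 0.26) * s
  if (malignant) {
    spike_amplitude <- runif(1, 0.3, 0.5)
    n_spikes <- sample(6:12, 1)
    lobe_count <- sample(1:3, 1)
    margin_sigma <- runif(1, 1.0, 2.0)
    calc_core <- runif(1) < 0.1
  } else {
    spike_amplitude <- runif(1, 0, 0.06)
    n_spikes <- 0L
    lobe_count <- 0L
    margin_sigma <- runif(1, 0.4, 1.0)
    calc_core <- runif(1) < 0.3
  }
  texture_type <- sample(1:3, 1, prob = c(0.15, 0.15, 0.7))
  base_intensity <- c(0.45, 0.6, 0.7)[texture_type]

  ctr <- rep((s + 1) / 2, 3)
  ax <- seq_len(s) - ctr[1]
  px <- rep(ax, times = s * s)
  py <- rep(rep(ax, each = s), times = s)
  pz <- rep(ax, each = s * s)
  u <- sqrt((px / radii[1])^2 + (py / radii[2])^2 + (pz / radii[3])^2)
  rr <- sqrt(px^2 + py^2 + pz^2)
  rr[rr == 0] <- 1e-9
  boost <- rep(0, length(u))
  if (n_spikes > 0 && spike_amplitude > 0) {
    for (i in seq_len(n_spikes)) {
      d <- rnorm(3); d <- d / sqrt(sum(d^2))
      dot <- (px * d[1] + py * d[2] + pz * d[3]) / rr
      boost <- pmax(boost, exp(12 * (dot - 1)))
    }
  }
  inside <- u <= 1 + spike_amplitude * boost
  if (lobe_count > 0) {
    for (i in seq_len(lobe_count)) {
      d <- rnorm(3); d <- d / sqrt(sum(d^2))
      rgeo <- 1 / sqrt(sum((d / radii)^2))
      lc <- d * rgeo
      lr <- 0.35 * min(radii)
      inside <- inside |
        ((px - lc[1])^2 + (py - lc[2])^2 + (pz - lc[3])^2 <= lr^2)
    }
  }
  true_mask <- array(as.integer(inside), c(s, s, s))

  layer <- array(base_intensity * inside, c(s, s, s))
  layer <- gaussian_blur3d(layer, margin_sigma)
  bg <- gaussian_blur3d(array(runif(s^3), c(s, s, s)), 1.5)
  bg <- 0.3 * (bg - min(bg)) / max(1e-12, max(bg) - min(bg))
  cube <- pmax(bg, layer)
  if (calc_core) {
    cr <- 0.15 * min(radii)
    core <- (px^2 + py^2 + pz^2) <= cr^2
    cube[core] <- 0.95
  }
  cube <- clip(cube, 0, 1)

  shape <- list(radii = radii, spike_amplitude = spike_amplitude,
                n_spikes = n_spikes, lobe_count = lobe_count,
                calc_core = calc_core, margin_sigma = margin_sigma,
                texture_type = texture_type,
                base_intensity = base_intensity)
  truth <- c(shape, list(
    latent_malignancy = latent_malignancy_score(spike_amplitude,
                                                lobe_count),
    semantic_true = true_semantic_scores(shape),
    true_mask = true_mask, center = round_half_up(ctr),
    malignant = malignant))
  list(cube = cube, truth = truth)
}

dice_coef <- function(a, b) {
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(1)
  2 * sum(a * b) / (sa + sb)
}

#' Simulate readers for one phantom
#'
#' Each reader's mask is the true mask randomly dilated or eroded by a
#' ball of radius up to `mask_jitter` (Dice against the truth >= 0.7
#' enforced by shrinking the radius); the malignancy rating is
#' `clip(round(latent + N(0, rating_noise_sd)), 1, 5)` (half-up
#' rounding); semantic scores are the true monotone shape maps plus
#' ordinal reader noise of +/-1 (absent when `rating_noise_sd` is 0).
#'
#' @param truth the `truth` element from [generate_truth()].
#' @param cfg a [phantom_config()].
#' @param nodule_id identifier stored on the annotations.
#' @return List of [reader_annotation()] objects, one per reader.
#' @export
simulate_readers <- function(truth, cfg, nodule_id = "nodule") {
  lapply(seq_len(cfg$readers), function(r) {
    mask <- truth$true_mask
    if (cfg$mask_jitter > 0L) {
      rad <- sample(0:cfg$mask_jitter, 1)
      dilate <- runif(1) < 0.5
      while (rad > 0L) {
        cand <- ball_morph3d(mask, rad, dilate)
        if (dice_coef(cand, truth$true_mask) >= 0.7 && sum(cand) > 0) {
          mask <- cand
          break
        }
        rad <- rad - 1L
      }
    }
    noisy <- cfg$rating_noise_sd > 0
    rating <- clip(round_half_up(truth$latent_malignancy +
                                   if (noisy)
                                     rnorm(1, 0, cfg$rating_noise_sd)
                                   else 0), 1, 5)
    sem <- truth$semantic_true
    if (noisy) {
      for (nm in names(sem)) {
        rg <- SEMANTIC_RANGES[[nm]]
        sem[[nm]] <- clip(sem[[nm]] +
                            sample(-1:1, 1, prob = c(0.25, 0.5, 0.25)),
                          rg[1], rg[2])
      }
    }
    center <- truth$center
    if (noisy) center <- center + sample(-1:1, 3, replace = TRUE)
    reader_annotation(reader_id = sprintf("r%02d", r),
                      nodule_key = nodule_id, center = center,
                      mask = mask, malignancy = rating,
                      semantic_scores = sem, scan_id = nodule_id,
                      slice_thickness = 1.75)
  })
}

#' Generate a full in-memory phantom dataset
#'
#' Produces one training sample per (nodule, reader): the shared nodule
#' cube, that reader's mask cube, the individual label from the reader's
#' rating, the panel label from all readers' ratings (`NA` when the mean
#' is exactly 3), and the eight binary semantic labels from the reader's
#' own scores. Nodules are assigned to train/validation/test (60/20/20,
#' stratified by class) at the nodule level.
#'
#' @param cfg a [phantom_config()].
#' @return List with `samples` (flat list), `nodules` (per-nodule truth,
#'   annotations, split), and `config`.
#' @export
build_phantom_set <- function(cfg) {
  n <- cfg$n_nodules
  nodules <- vector("list", n)
  samples <- list()
  if (n > 0) {
    set.seed(nodule_seed(cfg, 0L, salt = 3L))
    mal <- seq_len(n) <= round(cfg$malignant_fraction * n)
    split_id <- stratified_assign(as.integer(mal), 5L)
    split <- c("train", "train", "train", "validation", "test")[split_id]
  } else {
    split <- character(0)
  }
  for (i in seq_len(n)) {
    g <- generate_truth(cfg, i)
    set.seed(nodule_seed(cfg, i, salt = 1L))
    nid <- sprintf("n%04d", i)
    anns <- simulate_readers(g$truth, cfg, nodule_id = nid)
    ratings <- vapply(anns, `[[`, integer(1), "malignancy")
    pl <- panel_label(ratings)
    for (a in anns) {
      samples[[length(samples) + 1L]] <- list(
        cube = g$cube, mask = a$mask,
        individual = individual_label(a$malignancy), panel = pl,
        semantic = semantic_labels(a), nodule_id = nid,
        reader_id = a$reader_id, split = split[i])
    }
    nodules[[i]] <- list(nodule_id = nid, truth = g$truth, cube = g$cube,
                         annotations = anns, panel = pl, split = split[i])
  }
  list(samples = samples, nodules = nodules, config = cfg)
}

#' Write a phantom dataset to disk (NIfTI cubes + JSON manifest)
#'
#' Cubes and per-reader masks are written as NIfTI volumes with the
#' package's target voxel spacing; the manifest (0-based centres) is the
#' dialect [parse_annotations()] reads back.
#'
#' @param cfg a [phantom_config()].
#' @param dir output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
build_dataset <- function(cfg, dir) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stopf("build_dataset requires the RNifti package")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ds <- build_phantom_set(cfg)
  spacing <- c(0.68, 0.68, 1.75)
  nodules <- lapply(ds$nodules, function(nd) {
    cube_file <- paste0(nd$nodule_id, "_cube.nii.gz")
    RNifti::writeNifti(RNifti::asNifti(nd$cube, pixdim = spacing),
                       file.path(dir, cube_file))
    anns <- lapply(nd$annotations, function(a) {
      mf <- sprintf("%s_%s_mask.nii.gz", nd$nodule_id, a$reader_id)
      RNifti::writeNifti(RNifti::asNifti(a$mask * 1L, pixdim = spacing),
                         file.path(dir, mf))
      list(reader_id = a$reader_id, center = as.numeric(a$center) - 1,
           mask_file = mf, malignancy = a$malignancy,
           semantic = a$semantic_scores)
    })
    list(nodule_id = nd$nodule_id, scan_id = nd$nodule_id,
         slice_thickness = 1.75, cube_file = cube_file,
         panel_label = if (is.na(nd$panel)) NULL else nd$panel,
         split = nd$split, annotations = anns)
  })
  manifest <- list(format = "msnet3d-manifest", version = 1,
                   spacing = spacing, cube_side = cfg$cube_side,
                   seed = cfg$seed, nodules = nodules)
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

## ---- LIDC-style XML emission (for parser testing) ------------------------

## Ordered boundary contour of a binary slice: boundary pixels sorted by
## angle about the region centroid (phantom slices are star-shaped).
slice_contour <- function(m) {
  if (!any(m == 1)) return(NULL)
  m3 <- array(as.integer(m), c(dim(m), 1L))
  er <- ball_morph3d(m3, 1L, FALSE)[, , 1]
  b <- which(m == 1 & er == 0, arr.ind = TRUE)
  if (!nrow(b)) b <- which(m == 1, arr.ind = TRUE)
  ctr <- colMeans(which(m == 1, arr.ind = TRUE))
  ang <- atan2(b[, 2] - ctr[2], b[, 1] - ctr[1])
  rad <- sqrt((b[, 1] - ctr[1])^2 + (b[, 2] - ctr[2])^2)
  b[order(ang, rad), , drop = FALSE]
}

#' Write nodule records as LIDC-style XML
#'
#' One `readingSession` per reader with `unblindedReadNodule` elements
#' carrying the characteristics and per-slice edge-map contours; readable
#' by [parse_annotations()].
#'
#' @param records nodule records ([group_to_nodules()] format).
#' @param path output file.
#' @param scan_id,slice_thickness header metadata.
#' @return `path`, invisibly.
#' @export
write_lidc_xml <- function(records, path, scan_id = "scan-0001",
                           slice_thickness = 1.75) {
  doc <- xml2::xml_new_root("LidcReadMessage")
  hdr <- xml2::xml_add_child(doc, "ResponseHeader")
  xml2::xml_add_child(hdr, "SeriesInstanceUid", scan_id)
  xml2::xml_add_child(hdr, "SliceThickness",
                      format(slice_thickness, digits = 6))
  readers <- unique(unlist(lapply(records, function(r)
    vapply(r$annotations, `[[`, character(1), "reader_id"))))
  for (rd in readers) {
    sess <- xml2::xml_add_child(doc, "readingSession")
    xml2::xml_add_child(sess, "servicingRadiologistID", rd)
    for (rec in records) {
      for (a in rec$annotations) {
        if (a$reader_id != rd) next
        nod <- xml2::xml_add_child(sess, "unblindedReadNodule")
        xml2::xml_add_child(nod, "noduleID", rec$nodule_id)
        ch <- xml2::xml_add_child(nod, "characteristics")
        for (nm in SEMANTIC_FEATURES)
          xml2::xml_add_child(ch, nm, as.character(a$semantic_scores[[nm]]))
        xml2::xml_add_child(ch, "malignancy", as.character(a$malignancy))
        zs <- which(apply(a$mask, 3, function(sl) any(sl == 1)))
        for (z in zs) {
          cont <- slice_contour(a$mask[, , z])
          if (is.null(cont)) next
          roi <- xml2::xml_add_child(nod, "roi")
          xml2::xml_add_child(roi, "imageZposition", as.character(z - 1L))
          xml2::xml_add_child(roi, "inclusion", "TRUE")
          for (i in seq_len(nrow(cont))) {
            em <- xml2::xml_add_child(roi, "edgeMap")
            xml2::xml_add_child(em, "xCoord", as.character(cont[i, 1] - 1L))
            xml2::xml_add_child(em, "yCoord", as.character(cont[i, 2] - 1L))
          }
        }
      }
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}
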