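## Per-reader annotation handling: parsing (JSON manifest or LIDC-style
## XML), grouping into nodules, cohort filters and label generation.
## Cohort rules: individual cohort keeps annotations from nodules read by
## >= 3 radiologists on scans with slice thickness < 3 mm; malignancy 1-3
## maps to benign, 4-5 to malignant; the panel label is the mean rating
## (< 3 benign, > 3 malignant, exactly 3 excluded); calcification is
## binarised 1-5 vs 6, the other seven features 1-3 vs 4-5.

#' One reader's annotation of one nodule
#'
#' @param reader_id,nodule_key opaque identifiers.
#' @param center voxel coordinate triple (1-based, package-internal
#'   convention; manifests on disk are 0-based).
#' @param mask binary 3-d array in scan voxel coordinates.
#' @param malignancy integer malignancy rating 1-5.
#' @param semantic_scores named list/vector with the eight features of
#'   [semantic_features()]; ranges validated (calcification 1-6,
#'   internalStructure 1-4, others 1-5).
#' @param scan_id,slice_thickness scan metadata carried for cohort filters.
#' @return `msnet_reader_annotation` object.
#' @export
reader_annotation <- function(reader_id, nodule_key, center, mask,
                              malignancy, semantic_scores,
                              scan_id = NA_character_,
                              slice_thickness = NA_real_) {
  malignancy <- as.integer(malignancy)
  if (is.na(malignancy) || malignancy < 1L || malignancy > 5L)
    stopf("annotation %s/%s: malignancy rating %s out of range 1-5",
          nodule_key, reader_id, malignancy)
  ss <- lapply(semantic_scores, as.integer)
  missing <- setdiff(SEMANTIC_FEATURES, names(ss))
  if (length(missing))
    stopf("annotation %s/%s: missing semantic scores: %s", nodule_key,
          reader_id, paste(missing, collapse = ", "))
  for (nm in SEMANTIC_FEATURES) {
    rg <- SEMANTIC_RANGES[[nm]]
    if (is.na(ss[[nm]]) || ss[[nm]] < rg[1] || ss[[nm]] > rg[2])
      stopf("annotation %s/%s: %s score %s outside %d-%d", nodule_key,
            reader_id, nm, ss[[nm]], rg[1], rg[2])
  }
  if (!is.null(mask) && !is_binary_array(mask))
    stopf("annotation %s/%s: mask is not strictly binary", nodule_key,
          reader_id)
  structure(list(reader_id = as.character(reader_id),
                 nodule_key = as.character(nodule_key),
                 center = as.numeric(center), mask = mask,
                 malignancy = malignancy,
                 semantic_scores = ss[SEMANTIC_FEATURES],
                 scan_id = as.character(scan_id),
                 slice_thickness = as.numeric(slice_thickness)),
            class = "msnet_reader_annotation")
}

## ---- parsing -------------------------------------------------------------

#' Parse annotations from a JSON manifest or LIDC-style XML file
#'
#' The JSON manifest dialect (written by [build_dataset()]) is one object
#' per nodule with per-reader annotation records; masks are referenced as
#' NIfTI files relative to the manifest. LIDC-style XML carries per-reader
#' `unblindedReadNodule` elements with characteristics and per-slice ROI
#' edge-map contours, which are rasterised to binary masks
#' (`dims` must then give the scan grid).
#'
#' @param path manifest/XML path, or an already-deserialised manifest list.
#' @param dims integer triple: scan voxel grid, required for XML input.
#' @param load_masks read referenced mask volumes (requires RNifti);
#'   set `FALSE` to keep only file references.
#' @return List of [reader_annotation()] objects (empty for a document
#'   with no nodules).
#' @export
parse_annotations <- function(path, dims = NULL, load_masks = TRUE) {
  if (is.character(path) && grepl("\\.xml$", path, ignore.case = TRUE))
    return(parse_annotations_xml(path, dims))
  man <- if (is.character(path)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    path
  }
  base <- if (is.character(path)) dirname(path) else "."
  if (is.null(man$nodules)) stopf("manifest: missing 'nodules' element")
  out <- list()
  for (nd in man$nodules) {
    for (an in nd$annotations) {
      mask <- an[["mask"]]  # exact: `$` would partial-match mask_file
      if (is.null(mask) && !is.null(an[["mask_file"]]) && load_masks) {
        if (!requireNamespace("RNifti", quietly = TRUE))
          stopf("reading mask NIfTI files requires the RNifti package")
        mask <- as.array(RNifti::readNifti(file.path(base,
                                                     an[["mask_file"]])))
        mask <- (mask > 0.5) * 1L
      }
      out[[length(out) + 1L]] <- reader_annotation(
        reader_id = an[["reader_id"]], nodule_key = nd[["nodule_id"]],
        center = unlist(an[["center"]]) + 1,  # manifest is 0-based
        mask = mask, malignancy = an[["malignancy"]],
        semantic_scores = an[["semantic"]],
        scan_id = nd[["scan_id"]] %||% NA_character_,
        slice_thickness = nd[["slice_thickness"]] %||% NA_real_)
    }
  }
  out
}

parse_annotations_xml <- function(path, dims) {
  if (is.null(dims))
    stopf("parse_annotations: XML input requires the scan grid 'dims'")
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  scan_id <- xml2::xml_text(xml2::xml_find_first(
    doc, ".//ResponseHeader/SeriesInstanceUid"))
  thick <- as.numeric(xml2::xml_text(xml2::xml_find_first(
    doc, ".//ResponseHeader/SliceThickness")))
  out <- list()
  for (sess in xml2::xml_find_all(doc, ".//readingSession")) {
    reader <- xml2::xml_text(xml2::xml_find_first(
      sess, "./servicingRadiologistID"))
    for (nod in xml2::xml_find_all(sess, "./unblindedReadNodule")) {
      nid <- xml2::xml_text(xml2::xml_find_first(nod, "./noduleID"))
      chars <- xml2::xml_find_first(nod, "./characteristics")
      if (is.na(chars))
        stopf("XML nodule '%s': missing characteristics element", nid)
      getc <- function(nm) {
        v <- xml2::xml_text(xml2::xml_find_first(chars, paste0("./", nm)))
        if (is.na(v) || v == "")
          stopf("XML nodule '%s': missing characteristic '%s'", nid, nm)
        as.integer(v)
      }
      sem <- setNames(lapply(SEMANTIC_FEATURES, getc), SEMANTIC_FEATURES)
      mask <- array(0L, dims)
      for (roi in xml2::xml_find_all(nod, "./roi")) {
        z <- as.integer(round(as.numeric(xml2::xml_text(
          xml2::xml_find_first(roi, "./imageZposition"))))) + 1L
        if (z < 1L || z > dims[3])
          stopf("XML nodule '%s': ROI slice %d outside the scan", nid, z - 1L)
        xs <- as.numeric(xml2::xml_text(
          xml2::xml_find_all(roi, ".//xCoord"))) + 1
        ys <- as.numeric(xml2::xml_text(
          xml2::xml_find_all(roi, ".//yCoord"))) + 1
        if (!length(xs)) stopf("XML nodule '%s': empty edge map", nid)
        mask[, , z] <- mask[, , z] | fill_polygon(xs, ys, dims[1:2])
      }
      mask <- mask * 1L
      vox <- which(mask == 1L, arr.ind = TRUE)
      center <- if (nrow(vox)) round_half_up(colMeans(vox)) else
        rep(NA_real_, 3)
      out[[length(out) + 1L]] <- reader_annotation(
        reader_id = reader, nodule_key = nid, center = center, mask = mask,
        malignancy = getc("malignancy"), semantic_scores = sem,
        scan_id = scan_id, slice_thickness = thick)
    }
  }
  out
}

## Rasterise a closed contour (pixel-centre even-odd test, boundary pixels
## included) to a binary 2-d mask.
fill_polygon <- function(xs, ys, dims) {
  m <- matrix(FALSE, dims[1], dims[2])
  n <- length(xs)
  xi <- as.integer(round(xs)); yi <- as.integer(round(ys))
  ok <- xi >= 1 & xi <= dims[1] & yi >= 1 & yi <= dims[2]
  m[cbind(xi[ok], yi[ok])] <- TRUE  # the boundary itself is included
  if (n >= 3) {
    xr <- seq_len(dims[1]); yr <- seq_len(dims[2])
    grid_x <- rep(xr, times = dims[2]); grid_y <- rep(yr, each = dims[1])
    inside <- rep(FALSE, length(grid_x))
    j <- n
    for (i in seq_len(n)) {
      cross <- (ys[i] > grid_y) != (ys[j] > grid_y)
      xint <- xs[i] + (grid_y - ys[i]) / (ys[j] - ys[i]) * (xs[j] - xs[i])
      inside <- xor(inside, cross & !is.na(xint) & grid_x < xint)
      j <- i
    }
    m[cbind(grid_x[inside], grid_y[inside])] <- TRUE
  }
  m
}

## ---- grouping ------------------------------------------------------------

#' Group reader annotations into nodule records
#'
#' Annotations sharing an explicit `nodule_key` are grouped by key; when
#' keys are absent, single-linkage grouping by centroid distance is used.
#' A group is flagged ambiguous (not dropped here) when its centres spread
#' beyond the threshold.
#'
#' @param annotations list of [reader_annotation()] objects.
#' @param matching list; `max_center_dist` (voxels, default 5) is both the
#'   distance-grouping threshold and the ambiguity criterion.
#' @return List of nodule records: `nodule_id`, `scan_id`,
#'   `slice_thickness`, `annotations`, `ambiguous`.
#' @export
group_to_nodules <- function(annotations,
                             matching = list(max_center_dist = 5)) {
  if (!length(annotations)) return(list())
  thr <- matching$max_center_dist %||% 5
  keys <- vapply(annotations, function(a) a$nodule_key, character(1))
  have_keys <- !any(is.na(keys) | keys == "")
  if (have_keys) {
    groups <- split(seq_along(annotations), keys)
  } else {
    centers <- do.call(rbind, lapply(annotations, `[[`, "center"))
    assigned <- rep(NA_integer_, nrow(centers))
    gid <- 0L
    for (i in seq_len(nrow(centers))) {
      if (!is.na(assigned[i])) next
      gid <- gid + 1L
      queue <- i
      assigned[i] <- gid
      while (length(queue)) {
        cur <- queue[[1]]; queue <- queue[-1]
        d <- sqrt(colSums((t(centers) - centers[cur, ])^2))
        near <- which(is.na(assigned) & d <= thr)
        assigned[near] <- gid
        queue <- c(queue, near)
      }
    }
    groups <- split(seq_along(annotations), assigned)
  }
  lapply(groups, function(ix) {
    anns <- annotations[ix]
    centers <- do.call(rbind, lapply(anns, `[[`, "center"))
    spread <- if (nrow(centers) > 1L)
      max(stats::dist(centers)) else 0
    list(nodule_id = anns[[1]]$nodule_key,
         scan_id = anns[[1]]$scan_id,
         slice_thickness = anns[[1]]$slice_thickness,
         annotations = anns,
         ambiguous = spread > thr)
  })
}

## ---- cohort filters and labels -------------------------------------------

#' Individual-label cohort filter
#'
#' Keeps annotations only from nodule records read by at least three
#' radiologists on scans with slice thickness below 3 mm (records flagged
#' ambiguous are also dropped). Each retained annotation is an independent
#' training case.
#'
#' @param records output of [group_to_nodules()].
#' @return Flat list of retained [reader_annotation()] objects.
#' @export
filter_individual_cohort <- function(records) {
  out <- list()
  for (rec in records) {
    if (is.null(rec$slice_thickness) || is.na(rec$slice_thickness))
      stopf("nodule %s: slice thickness missing", rec$nodule_id)
    if (isTRUE(rec$ambiguous)) next
    if (length(rec$annotations) < 3L) next
    if (rec$slice_thickness >= 3) next
    out <- c(out, rec$annotations)
  }
  out
}

#' Binary individual label from one malignancy rating
#'
#' Ratings 1-3 are benign (0), 4-5 malignant (1).
#' @param malignancy integer rating 1-5.
#' @return 0L or 1L.
#' @export
individual_label <- function(malignancy) {
  m <- as.integer(malignancy)
  if (any(is.na(m) | m < 1L | m > 5L))
    stopf("malignancy rating out of range 1-5")
  as.integer(m >= 4L)
}

#' Binary panel label from all readers' ratings
#'
#' Mean rating below 3 is benign (0), above 3 malignant (1); a mean of
#' exactly 3 is excluded and returned as the sentinel `NA`.
#'
#' @param ratings non-empty integer vector of 1-5 ratings.
#' @return 0L, 1L, or `NA` (excluded).
#' @export
panel_label <- function(ratings) {
  if (!length(ratings)) stopf("panel_label: empty rating list")
  r <- as.integer(ratings)
  if (any(is.na(r) | r < 1L | r > 5L))
    stopf("panel_label: rating out of range 1-5")
  m <- mean(r)
  if (m < 3) 0L else if (m > 3) 1L else NA_integer_
}

#' Binarise one semantic-feature score
#'
#' Calcification: levels 1-5 form one category (0), level 6 the other (1).
#' All other features: levels 1-3 map to 0, levels 4 (and 5 where the
#' scale reaches 5) to 1.
#'
#' @param feature feature name (one of [semantic_features()]).
#' @param score integer score within the feature's range.
#' @return 0L or 1L.
#' @export
binarize_semantic <- function(feature, score) {
  if (!feature %in% SEMANTIC_FEATURES)
    stopf("unknown semantic feature '%s'", feature)
  rg <- SEMANTIC_RANGES[[feature]]
  s <- as.integer(score)
  if (any(is.na(s) | s < rg[1] | s > rg[2]))
    stopf("%s score %s outside %d-%d", feature, score, rg[1], rg[2])
  if (feature == "calcification") as.integer(s == 6L) else as.integer(s >= 4L)
}

#' All eight binary semantic labels for one annotation
#'
#' @param annotation a [reader_annotation()].
#' @return Named integer vector of length 8 in canonical feature order.
#' @export
semantic_labels <- function(annotation) {
  vapply(SEMANTIC_FEATURES, function(nm)
    binarize_semantic(nm, annotation$semantic_scores[[nm]]), integer(1))
}
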