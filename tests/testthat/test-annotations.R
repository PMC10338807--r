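test_that("individual label rule maps 1-3 to benign and 4-5 to malignant", {
  expect_identical(individual_label(1), 0L)
  expect_identical(individual_label(3), 0L)
  expect_identical(individual_label(4), 1L)
  expect_identical(individual_label(5), 1L)
  expect_error(individual_label(0), "out of range")
  expect_error(individual_label(6), "out of range")
  ## monotone non-decreasing in the rating
  labs <- vapply(1:5, individual_label, integer(1))
  expect_true(all(diff(labs) >= 0))
})

test_that("panel label uses the mean rating with exclusion at exactly 3", {
  expect_identical(panel_label(c(3, 3, 3)), NA_integer_)
  expect_identical(panel_label(c(5, 5, 4, 4)), 1L)
  expect_identical(panel_label(c(1, 2, 2, 3)), 0L)
  expect_error(panel_label(integer(0)), "empty")
  ## permutation invariance
  set.seed(1)
  for (i in 1:20) {
    r <- sample(1:5, sample(2:4, 1), replace = TRUE)
    expect_identical(panel_label(r), panel_label(sample(r)))
  }
})

test_that("semantic binarisation follows the per-feature level rules", {
  expect_identical(binarize_semantic("calcification", 6), 1L)
  expect_identical(binarize_semantic("calcification", 5), 0L)
  expect_identical(binarize_semantic("calcification", 1), 0L)
  expect_identical(binarize_semantic("margin", 4), 1L)
  expect_identical(binarize_semantic("margin", 3), 0L)
  expect_identical(binarize_semantic("internalStructure", 4), 1L)
  expect_identical(binarize_semantic("internalStructure", 3), 0L)
  expect_error(binarize_semantic("nope", 3), "unknown")
  expect_error(binarize_semantic("internalStructure", 5), "outside")
})

test_that("annotation validation rejects out-of-range ratings", {
  expect_error(make_annotation(malignancy = 7L), "out of range")
  bad <- setNames(as.list(rep(3L, 8)), semantic_features())
  bad$internalStructure <- 5L
  expect_error(make_annotation(scores = bad), "outside 1-4")
  bad$internalStructure <- 3L
  bad$calcification <- 7L
  expect_error(make_annotation(scores = bad), "outside 1-6")
})

test_that("grouping honours keys, distance matching, and flags ambiguity", {
  a4 <- lapply(paste0("r", 1:4), function(r)
    make_annotation(reader = r, nodule = "nod"))
  rec <- group_to_nodules(a4)
  expect_length(rec, 1L)
  expect_length(rec[[1]]$annotations, 4L)
  expect_false(rec[[1]]$ambiguous)

  ## centres 2 voxels apart with threshold 5: grouped
  b <- list(make_annotation(reader = "r1", nodule = "", center = c(9, 10, 10)),
            make_annotation(reader = "r2", nodule = "",
                            center = c(11, 10, 10)))
  b[[1]]$nodule_key <- ""
  b[[2]]$nodule_key <- ""
  rec <- group_to_nodules(b, matching = list(max_center_dist = 5))
  expect_length(rec, 1L)

  ## same key but centres far apart: ambiguous
  c2 <- list(make_annotation(reader = "r1", nodule = "k",
                             center = c(5, 5, 5), dims = c(60, 60, 60)),
             make_annotation(reader = "r2", nodule = "k",
                             center = c(45, 45, 45), dims = c(60, 60, 60)))
  rec <- group_to_nodules(c2, matching = list(max_center_dist = 5))
  expect_true(rec[[1]]$ambiguous)
})

test_that("individual cohort keeps >=3 readers and thickness < 3 mm", {
  r2 <- group_to_nodules(lapply(paste0("r", 1:2), function(r)
    make_annotation(reader = r, nodule = "a")))
  expect_length(filter_individual_cohort(r2), 0L)

  thick <- group_to_nodules(lapply(paste0("r", 1:4), function(r)
    make_annotation(reader = r, nodule = "b", slice_thickness = 3.0)))
  expect_length(filter_individual_cohort(thick), 0L)

  ok <- group_to_nodules(lapply(paste0("r", 1:4), function(r)
    make_annotation(reader = r, nodule = "c", slice_thickness = 1.75)))
  kept <- filter_individual_cohort(ok)
  expect_length(kept, 4L)

  ## output size is the sum of reader counts over qualifying records
  both <- group_to_nodules(c(
    lapply(paste0("r", 1:3), function(r)
      make_annotation(reader = r, nodule = "x")),
    lapply(paste0("r", 1:4), function(r)
      make_annotation(reader = r, nodule = "y")),
    lapply(paste0("r", 1:2), function(r)
      make_annotation(reader = r, nodule = "z"))))
  expect_length(filter_individual_cohort(both), 7L)

  missing <- r2
  missing[[1]]$slice_thickness <- NA_real_
  expect_error(filter_individual_cohort(missing), "thickness")
})

test_that("manifest with zero nodules parses to an empty list", {
  expect_identical(parse_annotations(list(nodules = list())), list())
})

test_that("in-memory manifest round-trips annotations", {
  man <- list(nodules = list(list(
    nodule_id = "n1", scan_id = "s1", slice_thickness = 1.75,
    annotations = list(list(
      reader_id = "r1", center = c(9, 9, 9),  # 0-based on disk
      mask = array(0L, c(20, 20, 20)), malignancy = 4,
      semantic = setNames(as.list(rep(3L, 8)), semantic_features()))))))
  anns <- parse_annotations(man)
  expect_length(anns, 1L)
  expect_identical(anns[[1]]$malignancy, 4L)
  expect_equal(anns[[1]]$center, c(10, 10, 10))  # 1-based internally
  expect_identical(anns[[1]]$semantic_scores$margin, 3L)
})

test_that("LIDC-style XML emission re-parses to the same annotations", {
  anns <- lapply(paste0("r", 1:2), function(r)
    make_annotation(reader = r, nodule = "n1", malignancy = 4L,
                    radius = 5))
  recs <- group_to_nodules(anns)
  path <- tempfile(fileext = ".xml")
  write_lidc_xml(recs, path, scan_id = "scan1")
  back <- parse_annotations(path, dims = c(20L, 20L, 20L))
  expect_length(back, 2L)
  expect_identical(back[[1]]$malignancy, 4L)
  expect_identical(back[[1]]$semantic_scores$texture, 3L)
  expect_equal(back[[1]]$slice_thickness, 1.75)
  ## rasterised masks reproduce the drawn segmentations
  for (i in 1:2) {
    a <- anns[[i]]
    b <- back[[which(vapply(back, `[[`, character(1), "reader_id") ==
                       a$reader_id)]]
    inter <- sum(a$mask * b$mask)
    dice <- 2 * inter / (sum(a$mask) + sum(b$mask))
    expect_gt(dice, 0.95)
  }
})
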