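small_cfg <- function(...) {
  do.call(phantom_config,
          modifyList(list(n_nodules = 6L, readers = 3L, cube_side = 24L,
                          malignant_fraction = 0.34, seed = 7L),
                     list(...)))
}

test_that("phantom generation is deterministic in (config, index)", {
  cfg <- small_cfg()
  g1 <- generate_truth(cfg, 2L)
  g2 <- generate_truth(cfg, 2L)
  expect_identical(g1, g2)
  g3 <- generate_truth(cfg, 3L)
  expect_false(identical(g1$cube, g3$cube))
  expect_true(all(g1$cube >= 0 & g1$cube <= 1))
  expect_true(all(g1$truth$true_mask %in% c(0L, 1L)))
})

test_that("latent malignancy is monotone in spike amplitude and lobes", {
  amps <- seq(0, 0.5, by = 0.05)
  l <- latent_malignancy_score(amps, 0)
  expect_true(all(diff(l) >= 0))
  expect_true(all(latent_malignancy_score(0.4, 0:3) ==
                    cummax(latent_malignancy_score(0.4, 0:3))))
  ## smooth phantoms sit in the benign band
  expect_lt(latent_malignancy_score(0.06, 0), 3)
  ## spiky, lobed ones are firmly malignant
  expect_gt(latent_malignancy_score(0.3, 1), 3.5)
})

test_that("smooth phantom masks match the analytic ellipsoid volume", {
  cfg <- phantom_config(n_nodules = 10L, cube_side = 32L,
                        malignant_fraction = 0.2, seed = 13L)
  ## indices beyond the malignant block are smooth benign shapes
  for (i in c(5L, 8L)) {
    g <- generate_truth(cfg, i)
    expect_equal(g$truth$lobe_count, 0L)
    analytic <- 4 / 3 * pi * prod(g$truth$radii)
    expect_lt(abs(sum(g$truth$true_mask) - analytic) / analytic, 0.1)
  }
})

test_that("noise-free readers reproduce the truth exactly", {
  cfg <- small_cfg(rating_noise_sd = 0, mask_jitter = 0L)
  g <- generate_truth(cfg, 1L)
  set.seed(1)
  anns <- simulate_readers(g$truth, cfg, "n1")
  expect_length(anns, 3L)
  for (a in anns) {
    expect_identical(a$mask, g$truth$true_mask)
    expect_identical(a$malignancy,
                     as.integer(floor(g$truth$latent_malignancy + 0.5)))
    expect_identical(unlist(a$semantic_scores),
                     unlist(lapply(g$truth$semantic_true, as.integer)))
  }
})

test_that("noisy reader masks stay within the enforced Dice band", {
  cfg <- small_cfg(rating_noise_sd = 0.7, mask_jitter = 2L)
  g <- generate_truth(cfg, 1L)
  set.seed(2)
  anns <- simulate_readers(g$truth, cfg, "n1")
  dice <- function(a, b) 2 * sum(a * b) / (sum(a) + sum(b))
  for (a in anns) {
    expect_gte(dice(a$mask, g$truth$true_mask), 0.7)
    expect_true(a$malignancy %in% 1:5)
  }
})

test_that("label disagreement rate matches the enumerated noise model", {
  ## readers rate clip(round(latent + N(0, sd)), 1, 5); with latent 3.5
  ## and sd 0.7 the enumerated probability that a 4-reader panel label
  ## differs from a single reader's label is compared against Monte Carlo
  latent <- 3.5; sdv <- 0.7
  rate_rating <- function(z) pmin(pmax(floor(latent + z + 0.5), 1), 5)
  set.seed(31)
  mc <- replicate(2000, {
    r <- rate_rating(rnorm(4, 0, sdv))
    m <- mean(r)
    pan <- if (m < 3) 0L else if (m > 3) 1L else NA_integer_
    ind <- as.integer(r[1] >= 4)
    !is.na(pan) && pan != ind
  })
  ## independent (quasi-exhaustive) oracle on a fine Gaussian grid
  qs <- stats::qnorm((1:399) / 400, 0, sdv)
  ratings <- rate_rating(qs)
  p_r <- table(factor(ratings, 1:5)) / length(ratings)
  combos <- expand.grid(r1 = 1:5, r2 = 1:5, r3 = 1:5, r4 = 1:5)
  pw <- p_r[combos$r1] * p_r[combos$r2] * p_r[combos$r3] * p_r[combos$r4]
  m <- rowMeans(combos)
  pan <- ifelse(m < 3, 0L, ifelse(m > 3, 1L, NA_integer_))
  ind <- as.integer(combos$r1 >= 4)
  p_disagree <- sum(pw[!is.na(pan) & pan != ind]) / sum(pw)
  expect_lt(abs(mean(mc) - p_disagree), 0.02)
})

test_that("in-memory dataset is internally consistent with the label rules", {
  cfg <- small_cfg()
  ds <- build_phantom_set(cfg)
  expect_length(ds$samples, 6L * 3L)
  expect_length(build_phantom_set(small_cfg(n_nodules = 0L))$samples, 0L)
  ## realised malignant fraction exact to rounding
  mal <- vapply(ds$nodules, function(n) n$truth$malignant, logical(1))
  expect_equal(sum(mal), round(0.34 * 6))
  for (nd in ds$nodules) {
    ratings <- vapply(nd$annotations, `[[`, integer(1), "malignancy")
    expect_identical(nd$panel, panel_label(ratings))
  }
  for (s in ds$samples[1:6]) {
    expect_true(all(s$semantic %in% 0:1))
    expect_true(s$split %in% c("train", "validation", "test"))
  }
})

test_that("manifest on disk round-trips through the annotations module", {
  cfg <- phantom_config(n_nodules = 3L, readers = 2L, cube_side = 20L,
                        malignant_fraction = 0.34, seed = 5L)
  dir <- tempfile("phantoms")
  path <- build_dataset(cfg, dir)
  expect_true(file.exists(path))
  man <- jsonlite::read_json(path)
  expect_length(man$nodules, 3L)
  anns <- parse_annotations(path)
  expect_length(anns, 6L)
  ds <- build_phantom_set(cfg)
  ## re-parsed annotations equal those emitted
  for (i in seq_along(anns)) {
    orig <- ds$nodules[[ceiling(i / 2)]]$annotations[[(i - 1) %% 2 + 1]]
    expect_identical(anns[[i]]$malignancy, orig$malignancy)
    expect_equal(sum(abs(anns[[i]]$mask - orig$mask)), 0)
    expect_identical(unlist(anns[[i]]$semantic_scores),
                     unlist(orig$semantic_scores))
  }
  ## stored panel labels agree with recomputation from emitted ratings
  recs <- group_to_nodules(anns)
  for (nd in man$nodules) {
    rec <- recs[[nd$nodule_id]]
    stored <- if (is.null(nd$panel_label)) NA_integer_ else
      as.integer(nd$panel_label)
    expect_identical(panel_label(vapply(rec$annotations, `[[`, integer(1),
                                        "malignancy")), stored)
  }
})
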