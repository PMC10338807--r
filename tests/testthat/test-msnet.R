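test_that("prediction heads emit a probability pair on the simplex", {
  m <- tiny_model(seed = 41L)
  set.seed(41)
  shared <- rnorm(64)
  p <- head_forward(m$heads$individual, shared)
  expect_length(p, 2L)
  expect_equal(sum(p), 1, tolerance = 1e-12)
  expect_true(all(p >= 0))
  ## zeroed final layer: softmax of equal logits = (0.5, 0.5)
  m0 <- m
  m0$heads$individual[[5]]$params$W[] <- 0
  m0$heads$individual[[5]]$params$b[] <- 0
  expect_equal(head_forward(m0$heads$individual, shared), c(0.5, 0.5))
  ## deterministic in evaluation mode
  expect_identical(head_forward(m$heads$individual, shared),
                   head_forward(m$heads$individual, shared))
  expect_error(head_forward(m$heads$individual, rnorm(10)), "length")
})

test_that("FDID runs ten parallel heads on one shared backbone pass", {
  m <- tiny_model(seed = 42L)
  set.seed(42)
  cube <- array(runif(16^3), rep(16, 3))
  mask <- array(rbinom(16^3, 1, 0.2), rep(16, 3))
  out <- fdid_forward(m, cube, mask)
  expect_s3_class(out, "msnet_fdid_output")
  vecs <- c(out$semantic, list(out$individual, out$panel))
  expect_length(vecs, 10L)
  for (v in vecs) expect_equal(sum(v), 1, tolerance = 1e-6)
  ## observer-specific channel: a different mask changes the outputs
  mask2 <- array(rbinom(16^3, 1, 0.2), rep(16, 3))
  out2 <- fdid_forward(m, cube, mask2)
  expect_false(identical(out$individual, out2$individual))
  ## degenerate all-zero mask is well-defined
  expect_s3_class(fdid_forward(m, cube, array(0, rep(16, 3))),
                  "msnet_fdid_output")
  expect_error(fdid_forward(m, cube, mask * 0.5), "binary")
  expect_error(fdid_forward(m, cube[1:8, , ], mask), "identical dims")
})

test_that("heads are conditionally independent given the shared feature", {
  m <- tiny_model(seed = 43L)
  set.seed(43)
  cube <- array(runif(16^3), rep(16, 3))
  mask <- array(rbinom(16^3, 1, 0.2), rep(16, 3))
  base <- fdid_forward(m, cube, mask)
  m2 <- m
  for (i in seq_along(m2$heads$spiculation))
    for (nm in names(m2$heads$spiculation[[i]]$params))
      m2$heads$spiculation[[i]]$params[[nm]][] <- 0
  zeroed <- fdid_forward(m2, cube, mask)
  expect_equal(zeroed$semantic$spiculation, c(0.5, 0.5))
  for (nm in setdiff(semantic_features(), "spiculation"))
    expect_identical(base$semantic[[nm]], zeroed$semantic[[nm]])
  expect_identical(base$individual, zeroed$individual)
  expect_identical(base$panel, zeroed$panel)
})

test_that("fusion concatenates the ten pairs in canonical order", {
  m <- tiny_model(seed = 44L)
  set.seed(44)
  out <- fdid_forward(m, array(runif(16^3), rep(16, 3)),
                      array(rbinom(16^3, 1, 0.2), rep(16, 3)))
  fu <- fuse_predictions(out)
  expect_length(fu, 20L)
  ## consecutive pairs inherit the simplex property
  for (i in seq(1, 19, by = 2))
    expect_equal(fu[i] + fu[i + 1], 1, tolerance = 1e-9)
  expect_equal(fu[1:2], out$semantic$subtlety)
  expect_equal(fu[17:18], out$individual)
  expect_equal(fu[19:20], out$panel)
})

test_that("DR refines the fused predictions into two simplex vectors", {
  m <- tiny_model(seed = 45L)
  set.seed(45)
  fu <- runif(20)
  dr <- dr_forward(m, fu)
  expect_s3_class(dr, "msnet_dr_output")
  expect_equal(sum(dr$individual_refined), 1, tolerance = 1e-12)
  expect_equal(sum(dr$panel_refined), 1, tolerance = 1e-12)
  expect_error(dr_forward(m, runif(10)), "length-20")
  ## zero final layers: both outputs are (0.5, 0.5)
  m0 <- m
  for (nm in names(m0$dr)) {
    m0$dr[[nm]][[4]]$params$W[] <- 0
    m0$dr[[nm]][[4]]$params$b[] <- 0
  }
  dr0 <- dr_forward(m0, fu)
  expect_equal(dr0$individual_refined, c(0.5, 0.5))
  expect_equal(dr0$panel_refined, c(0.5, 0.5))
})

test_that("full forward returns twelve vectors and wires DR to FDID", {
  m <- tiny_model(seed = 46L)
  set.seed(46)
  cube <- array(runif(16^3), rep(16, 3))
  mask <- array(rbinom(16^3, 1, 0.2), rep(16, 3))
  r <- msnet_forward(m, cube, mask)
  n_vec <- length(r$fdid$semantic) + 2L + 2L
  expect_equal(n_vec, 12L)
  ## DR input equals FDID output exactly
  expect_identical(r$dr, dr_forward(m, fuse_predictions(r$fdid)))
  ## end-to-end determinism in evaluation mode
  r2 <- msnet_forward(m, cube, mask)
  expect_identical(r, r2)
  rec <- prediction_record(r$fdid, r$dr)
  expect_named(rec, c("semantic", "individual", "panel",
                      "refined_individual", "refined_panel"))
})

test_that("joint-stage gradients from the DR loss reach FDID parameters", {
  ns <- asNamespace("msnet3d")
  m <- tiny_model(seed = 47L)
  set.seed(47)
  x <- array(runif(16^3 * 2 * 2), c(16, 16, 16, 2, 2))
  fw <- ns$net_fw(m, x, training = FALSE, keep = TRUE, run_dr = TRUE)
  ## gradient only at the DR logits; no direct head-loss gradient
  zero_heads <- setNames(lapply(1:10, function(i) matrix(0, 2, 2)),
                         c(semantic_features(), "individual", "panel"))
  g_dr <- list(individual = matrix(c(1, -1, 0.5, -0.5), 2, 2),
               panel = matrix(0, 2, 2))
  bw <- ns$net_bw(m, fw, zero_heads, g_dr)
  ## a backbone weight gradient is non-zero: DR reaches the extractor
  expect_gt(max(abs(bw$grads$backbone$fc$W)), 0)
  expect_gt(max(abs(bw$grads$heads$individual[[1]]$W)), 0)
  ## finite-difference confirmation on one FDID head parameter
  probe_loss <- function(model) {
    f <- ns$net_fw(model, x, training = FALSE, keep = FALSE, run_dr = TRUE)
    sum(f$dr_logits$individual * g_dr$individual)
  }
  eps <- 1e-5
  mp <- m; mp$heads$panel[[1]]$params$W[1] <- mp$heads$panel[[1]]$params$W[1] + eps
  mm <- m; mm$heads$panel[[1]]$params$W[1] <- mm$heads$panel[[1]]$params$W[1] - eps
  fd <- (probe_loss(mp) - probe_loss(mm)) / (2 * eps)
  expect_equal(bw$grads$heads$panel[[1]]$W[1], fd, tolerance = 1e-4)
})

test_that("checkpoint save/load round-trips bit-identically", {
  m <- tiny_model(seed = 48L)
  path <- tempfile(fileext = ".rds")
  msnet_save(m, path)
  m2 <- msnet_load(path)
  expect_identical(m, m2)
  expect_true(file.exists(sub("\\.rds$", ".json", path)))
  set.seed(48)
  cube <- array(runif(16^3), rep(16, 3))
  mask <- array(rbinom(16^3, 1, 0.2), rep(16, 3))
  expect_identical(msnet_forward(m, cube, mask),
                   msnet_forward(m2, cube, mask))
})
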