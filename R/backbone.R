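## 3D-BcResNet50: the shared parameter extractor. A 7^3/stride-2 stem is
## followed by four residual stages whose bottleneck blocks replace the
## middle 3x3x3 convolution with a "bottleneck convolution" (BConv): the
## channels are split into parallel grouped convolutions of kernel sizes
## 7/5/3 and re-concatenated. Global average pooling plus a fully
## connected layer yield the 1024-d shared feature.

branch_spec <- function(kernel, width, groups) {
  if (kernel %% 2L == 0L) stopf("branch kernel must be odd")
  if (width %% groups != 0L) stopf("branch width must be divisible by groups")
  list(kernel = as.integer(kernel), width = as.integer(width),
       groups = as.integer(groups))
}

stage_spec <- function(reduce, branches, expand, blocks, downsample) {
  widths <- vapply(branches, `[[`, integer(1), "width")
  if (sum(widths) != reduce)
    stopf("stage: branch widths sum to %d, reduce width is %d",
          sum(widths), reduce)
  list(reduce = as.integer(reduce), branches = branches,
       expand = as.integer(expand), blocks = as.integer(blocks),
       downsample = downsample)
}

#' Default backbone configuration (3D-BcResNet50)
#'
#' The published stage table: a 7x7x7 stride-2 stem (64 channels), four
#' stages of bottleneck blocks (3/4/6/3 blocks; reduce widths 48/96/192/384,
#' 4x expansion) whose BConv branch layouts are
#' stage 1: (7,8,G8) (5,8,G4) (3,16,G1) (5,8,G4) (7,8,G8);
#' stage 2: (7,16,G8) (5,16,G4) (3,32,G1) (5,16,G4) (7,16,G8);
#' stage 3: (5,48,G4) (3,96,G1) (5,48,G4);
#' stage 4: (3,384,G1);
#' followed by global average pooling and a 1536-to-1024 fully connected
#' layer. An 80^3 two-channel input traverses spatial sizes 40/20/10/5.
#'
#' @return A backbone configuration list (class `msnet_backbone_config`).
#' @export
msnet_default_config <- function() {
  stages <- list(
    stage_spec(48L, list(branch_spec(7, 8, 8), branch_spec(5, 8, 4),
                         branch_spec(3, 16, 1), branch_spec(5, 8, 4),
                         branch_spec(7, 8, 8)), 192L, 3L, FALSE),
    stage_spec(96L, list(branch_spec(7, 16, 8), branch_spec(5, 16, 4),
                         branch_spec(3, 32, 1), branch_spec(5, 16, 4),
                         branch_spec(7, 16, 8)), 384L, 4L, TRUE),
    stage_spec(192L, list(branch_spec(5, 48, 4), branch_spec(3, 96, 1),
                          branch_spec(5, 48, 4)), 768L, 6L, TRUE),
    stage_spec(384L, list(branch_spec(3, 384, 1)), 1536L, 3L, TRUE)
  )
  structure(list(input_channels = 2L, input_side = 80L, stem_width = 64L,
                 stem_kernel = 7L, stem_stride = 2L, stages = stages,
                 feature_dim = 1024L),
            class = "msnet_backbone_config")
}

#' Reduced backbone configuration for CPU-scale runs
#'
#' Quarter-width variant of [msnet_default_config()] on 32^3 cubes with
#' halved block counts (2/2/3/2 by default) and a 256-d shared feature,
#' intended for desk-scale training and tests; the architecture (stem,
#' BConv branch pattern, 4x expansion, stage ladder) is unchanged. The
#' micro training profile used in the learning-sanity checks reduces
#' depth further to one block per stage, which optimises far better in
#' the few epochs a CPU run affords.
#'
#' @param input_side cube side in voxels (default 32).
#' @param feature_dim shared-feature dimension (default 256).
#' @param blocks per-stage block counts (length 4).
#' @return A backbone configuration list.
#' @export
msnet_reduced_config <- function(input_side = 32L, feature_dim = 256L,
                                 blocks = c(2L, 2L, 3L, 2L)) {
  blocks <- as.integer(blocks)
  stages <- list(
    stage_spec(12L, list(branch_spec(7, 2, 2), branch_spec(5, 2, 2),
                         branch_spec(3, 4, 1), branch_spec(5, 2, 2),
                         branch_spec(7, 2, 2)), 48L, blocks[1], FALSE),
    stage_spec(24L, list(branch_spec(7, 4, 4), branch_spec(5, 4, 2),
                         branch_spec(3, 8, 1), branch_spec(5, 4, 2),
                         branch_spec(7, 4, 4)), 96L, blocks[2], TRUE),
    stage_spec(48L, list(branch_spec(5, 12, 4), branch_spec(3, 24, 1),
                         branch_spec(5, 12, 4)), 192L, blocks[3], TRUE),
    stage_spec(96L, list(branch_spec(3, 96, 1)), 384L, blocks[4], TRUE)
  )
  structure(list(input_channels = 2L, input_side = as.integer(input_side),
                 stem_width = 16L, stem_kernel = 7L, stem_stride = 2L,
                 stages = stages, feature_dim = as.integer(feature_dim)),
            class = "msnet_backbone_config")
}

branch_widths <- function(stage) vapply(stage$branches, `[[`, integer(1),
                                        "width")

## ---- construction --------------------------------------------------------

build_bconv <- function(stage) {
  branches <- lapply(stage$branches, function(br) {
    list(layer_conv3d(br$kernel, br$width, br$width, stride = 1L,
                      groups = br$groups),
         layer_bn(br$width), layer_relu())
  })
  list(branches = branches, widths = branch_widths(stage))
}

build_block <- function(in_ch, stage, first) {
  stride <- if (first && stage$downsample) 2L else 1L
  proj <- NULL
  if (first && (in_ch != stage$expand || stride > 1L))
    proj <- list(layer_conv3d(1L, in_ch, stage$expand, stride = stride),
                 layer_bn(stage$expand))
  list(entry = list(layer_conv3d(1L, in_ch, stage$reduce, stride = stride),
                    layer_bn(stage$reduce), layer_relu()),
       bconv = build_bconv(stage),
       exit = list(layer_conv3d(1L, stage$reduce, stage$expand),
                   layer_bn(stage$expand)),
       proj = proj)
}

#' Construct an (uninitialised) backbone from a configuration
#'
#' Weights are zero until [init_weights()] is applied.
#' @param config a backbone configuration, e.g. [msnet_default_config()].
#' @return Backbone object (class `msnet_backbone`).
#' @export
build_backbone <- function(config) {
  stem <- list(layer_conv3d(config$stem_kernel, config$input_channels,
                            config$stem_width, stride = config$stem_stride),
               layer_bn(config$stem_width), layer_relu())
  stages <- vector("list", length(config$stages))
  in_ch <- config$stem_width
  for (s in seq_along(config$stages)) {
    st <- config$stages[[s]]
    blocks <- vector("list", st$blocks)
    for (b in seq_len(st$blocks)) {
      blocks[[b]] <- build_block(in_ch, st, first = b == 1L)
      in_ch <- st$expand
    }
    stages[[s]] <- blocks
  }
  fc <- layer_fc(in_ch, config$feature_dim)
  structure(list(stem = stem, stages = stages, fc = fc, config = config),
            class = "msnet_backbone")
}

## ---- forward / backward --------------------------------------------------

bconv_fw <- function(bc, x, training, keep) {
  parts <- split_channels(x, bc$widths)
  caches <- vector("list", length(parts))
  for (i in seq_along(parts)) {
    r <- seq_forward(bc$branches[[i]], parts[[i]], training, keep)
    parts[[i]] <- r$y
    caches[[i]] <- r$caches
    bc$branches[[i]] <- r$layers
  }
  list(y = concat_channels(parts), caches = caches, bc = bc)
}

bconv_bw <- function(bc, caches, gy) {
  parts <- split_channels(gy, bc$widths)
  grads <- vector("list", length(parts))
  for (i in seq_along(parts)) {
    r <- seq_backward(bc$branches[[i]], caches[[i]], parts[[i]])
    parts[[i]] <- r$gx
    grads[[i]] <- r$grads
  }
  list(gx = concat_channels(parts), grads = list(branches = grads))
}

block_fw <- function(block, x, training, keep) {
  e <- seq_forward(block$entry, x, training, keep)
  bc <- bconv_fw(block$bconv, e$y, training, keep)
  ex <- seq_forward(block$exit, bc$y, training, keep)
  if (is.null(block$proj)) {
    s_y <- x
    s_cache <- NULL
  } else {
    sr <- seq_forward(block$proj, x, training, keep)
    s_y <- sr$y
    s_cache <- sr$caches
    block$proj <- sr$layers
  }
  pre <- ex$y + s_y
  mask <- pre > 0
  block$entry <- e$layers
  block$bconv <- bc$bc
  block$exit <- ex$layers
  cache <- if (keep) list(entry = e$caches, bconv = bc$caches,
                          exit = ex$caches, proj = s_cache, mask = mask)
  list(y = pre * mask, cache = cache, block = block)
}

block_bw <- function(block, cache, gy) {
  gz <- gy * cache$mask
  ex <- seq_backward(block$exit, cache$exit, gz)
  bc <- bconv_bw(block$bconv, cache$bconv, ex$gx)
  en <- seq_backward(block$entry, cache$entry, bc$gx)
  if (is.null(block$proj)) {
    gx <- en$gx + gz
    proj_g <- NULL
  } else {
    pr <- seq_backward(block$proj, cache$proj, gz)
    gx <- en$gx + pr$gx
    proj_g <- pr$grads
  }
  list(gx = gx,
       grads = list(entry = en$grads, bconv = bc$grads, exit = ex$grads,
                    proj = proj_g))
}

backbone_fw <- function(bb, x, training = FALSE, keep = training) {
  stem <- seq_forward(bb$stem, x, training, keep)
  bb$stem <- stem$layers
  y <- stem$y
  spatial <- c(dim(y)[1])
  caches <- list(stem = stem$caches, stages = list())
  for (s in seq_along(bb$stages)) {
    scache <- vector("list", length(bb$stages[[s]]))
    for (b in seq_along(bb$stages[[s]])) {
      r <- block_fw(bb$stages[[s]][[b]], y, training, keep)
      y <- r$y
      scache[[b]] <- r$cache
      bb$stages[[s]][[b]] <- r$block
    }
    caches$stages[[s]] <- scache
    spatial <- c(spatial, dim(y)[1])
  }
  d <- dim(y)
  S <- prod(d[1:3])
  pooled <- matrix(.colMeans(matrix(y, S, d[4] * d[5]), S, d[4] * d[5]),
                   d[4], d[5])
  fcr <- layer_forward(bb$fc, pooled, training, keep)
  bb$fc <- fcr$layer
  caches$pool_dim <- d
  caches$fc <- fcr$cache
  list(feat = fcr$y, caches = if (keep) caches else NULL,
       spatial = spatial, bb = bb)
}

backbone_bw <- function(bb, caches, gfeat) {
  fcb <- layer_backward(bb$fc, caches$fc, gfeat)
  d <- caches$pool_dim
  S <- prod(d[1:3])
  gy <- array(rep(fcb$gx / S, each = S), d)
  stage_grads <- vector("list", length(bb$stages))
  for (s in rev(seq_along(bb$stages))) {
    bg <- vector("list", length(bb$stages[[s]]))
    for (b in rev(seq_along(bb$stages[[s]]))) {
      r <- block_bw(bb$stages[[s]][[b]], caches$stages[[s]][[b]], gy)
      gy <- r$gx
      bg[[b]] <- r$grads
    }
    stage_grads[[s]] <- bg
  }
  stem <- seq_backward(bb$stem, caches$stem, gy, need_input_grad = FALSE)
  list(gx = stem$gx,
       grads = list(stem = stem$grads, stages = stage_grads,
                    fc = fcb$grads))
}

#' Run the shared parameter extractor
#'
#' Maps a 2-channel cubic input (concatenated nodule and mask cubes) to the
#' shared feature vector via stem, four BConv stages, global average
#' pooling and a fully connected layer. Deterministic in evaluation mode.
#'
#' @param backbone a built (and initialised) backbone.
#' @param input array of dims (side, side, side, 2) for one sample, or
#'   (side, side, side, 2, N) for a batch.
#' @return Numeric vector of length `feature_dim` (or matrix
#'   `feature_dim x N`), with attribute `spatial_sizes` recording the
#'   per-stage spatial side lengths.
#' @export
backbone_forward <- function(backbone, input) {
  d <- dim(input)
  if (length(d) == 4L) dim(input) <- c(d, 1L)
  d <- dim(input)
  cfgc <- backbone$config$input_channels
  if (length(d) != 5L || d[4] != cfgc)
    stopf("backbone_forward: expected a (side,side,side,%d[,N]) array", cfgc)
  if (!all(is.finite(input))) stopf("backbone_forward: non-finite input")
  r <- backbone_fw(backbone, input, training = FALSE, keep = FALSE)
  out <- if (ncol(r$feat) == 1L) drop(r$feat) else r$feat
  attr(out, "spatial_sizes") <- r$spatial
  out
}

#' Count learnable parameters of a backbone configuration
#'
#' Analytic count (convolutions via the grouped-convolution formula
#' k^3 * Cin/G * Cout, batch-norm 2 per channel, fully connected
#' in x out + out), decomposable per component.
#'
#' @param config backbone configuration.
#' @param by_stage if `TRUE`, return a named breakdown instead of a total.
#' @return Integer total (or named numeric vector).
#' @export
parameter_count <- function(config, by_stage = FALSE) {
  conv_p <- function(k, cin, cout, g) k^3 * (cin / g) * cout
  bn_p <- function(ch) 2 * ch
  stem <- conv_p(config$stem_kernel, config$input_channels,
                 config$stem_width, 1) + bn_p(config$stem_width)
  in_ch <- config$stem_width
  per_stage <- numeric(length(config$stages))
  for (s in seq_along(config$stages)) {
    st <- config$stages[[s]]
    tot <- 0
    for (b in seq_len(st$blocks)) {
      tot <- tot + conv_p(1, in_ch, st$reduce, 1) + bn_p(st$reduce)
      for (br in st$branches)
        tot <- tot + conv_p(br$kernel, br$width, br$width, br$groups) +
          bn_p(br$width)
      tot <- tot + conv_p(1, st$reduce, st$expand, 1) + bn_p(st$expand)
      if (b == 1L && (in_ch != st$expand || st$downsample))
        tot <- tot + conv_p(1, in_ch, st$expand, 1) + bn_p(st$expand)
      in_ch <- st$expand
    }
    per_stage[s] <- tot
  }
  fc <- in_ch * config$feature_dim + config$feature_dim
  out <- c(stem = stem, setNames(per_stage,
                                 paste0("stage", seq_along(per_stage))),
           fc = fc)
  if (by_stage) out else sum(out)
}
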