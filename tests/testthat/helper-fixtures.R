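## Shared fixture builders. Everything is generated in code; sizes are kept
## small so the whole suite stays fast on one CPU.

## A deterministic annotation with a spherical mask.
make_annotation <- function(reader = "r1", nodule = "n1", malignancy = 3L,
                            center = c(10, 10, 10), dims = c(20, 20, 20),
                            radius = 4, scores = NULL,
                            slice_thickness = 1.75) {
  if (is.null(scores))
    scores <- setNames(as.list(rep(3L, 8)), semantic_features())
  ax <- lapply(1:3, function(a) seq_len(dims[a]) - center[a])
  g <- expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]])
  mask <- array(as.integer(g$x^2 + g$y^2 + g$z^2 <= radius^2), dims)
  reader_annotation(reader, nodule, center, mask, malignancy, scores,
                    scan_id = "scan1", slice_thickness = slice_thickness)
}

## Tiny reduced model for architecture tests (16^3 input).
tiny_model <- function(seed = 1L) {
  msnet_model(msnet_reduced_config(input_side = 16L, feature_dim = 64L),
              head_hidden = 16L, dr_hidden = 8L, seed = seed)
}

tiny_sample <- function(seed = 1L, side = 16L, individual = 0L,
                        panel = individual) {
  set.seed(seed)
  list(cube = array(runif(side^3), rep(side, 3)),
       mask = array(rbinom(side^3, 1, 0.1), rep(side, 3)),
       individual = individual, panel = panel,
       semantic = setNames(rep(0L, 8), semantic_features()),
       nodule_id = paste0("n", seed), reader_id = "r1")
}
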