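## Canonical order of the eight LIDC semantic (perceptible empirical)
## features; fixed because the 20-d fusion vector fed to the DR module
## depends on it.
SEMANTIC_FEATURES <- c(
  "subtlety", "internalStructure", "calcification", "sphericity",
  "margin", "lobulation", "spiculation", "texture"
)

## Rating range per semantic feature (LIDC convention).
SEMANTIC_RANGES <- list(
  subtlety = c(1L, 5L), internalStructure = c(1L, 4L),
  calcification = c(1L, 6L), sphericity = c(1L, 5L), margin = c(1L, 5L),
  lobulation = c(1L, 5L), spiculation = c(1L, 5L), texture = c(1L, 5L)
)
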