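# Small, fast phantom used across tests (coarse grid, few slices).
tiny_spec <- function(seed = 1L, noise = 0.05, arms = "down") {
  random_phantom_spec(seed, noise = noise, arms = arms, grid_n = 64L,
                      n_slices = c(axial = 8L, sagittal = 8L, coronal = 6L))
}

tiny_phantom <- function(seed = 1L, ...) generate_phantom(tiny_spec(seed, ...))

tiny_cases <- function(n, head_size, resolution = 32L, seed_offset = 0L) {
  lapply(seq_len(n), function(i) {
    build_case(tiny_phantom(i + seed_offset), head_size, resolution,
               id = sprintf("case_%03d", i))
  })
}
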