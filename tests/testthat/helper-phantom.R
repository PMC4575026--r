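# small phantoms used across test files; all geometry desk-scale

tiny_spec <- function(muscle_t2 = 24.83, lesion_fraction = 0,
                      grid = c(32, 32, 8), snr = Inf, seed = 11L,
                      lesion_t2 = 40) {
  phantom_spec(grid = grid,
               tissues = default_tissues(muscle_t2 = muscle_t2,
                                         lesion_t2 = lesion_t2),
               lesion_fraction = lesion_fraction,
               snr_te14 = snr, seed = seed)
}

tiny_phantom <- function(...) {
  sp <- tiny_spec(...)
  lm <- build_labelmap(sp)
  vol <- simulate_dual_echo(lm, sp$tissues, snr_te14 = sp$snr_te14,
                            seed = sp$seed)
  list(spec = sp, labelmap = lm, volume = vol)
}

# a label_map wrapping a bare integer array with unit voxels
bare_labelmap <- function(arr, voxel_size = c(1, 1, 1)) {
  label_map(arr, voxel_size = voxel_size)
}

# a t2_map built directly from a vector of pixel values (one slice)
map_from_values <- function(values) {
  t2 <- array(values, dim = c(length(values), 1, 1))
  t2_map(t2, valid = array(TRUE, dim(t2)), te_delta = 26)
}
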