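# Shared scene configurations for tests.

config_with <- function(base, ...) {
  over <- list(...)
  base[names(over)] <- over
  do.call(scene_config, base)
}

# Small, fast scene used by unit tests.
small_scene_config <- function(seed = 1L, ...) {
  config_with(list(image_height = 128L, image_width = 128L, n_osteocytes = 4L,
                   osteocyte_axes_range = c(4, 7), connection_radius = 80,
                   dead_end_rate = 1, seed = seed), ...)
}

# Noise-free variant (exact ground-truth rendering).
clean_scene_config <- function(seed = 1L, ...) {
  small_scene_config(seed = seed, noise_sd = 0, illumination_gradient = 0, ...)
}

# Tiny fields for training smoke tests (64 x 64, two somas).
train_scene_config <- function(seed = 1L, ...) {
  config_with(list(image_height = 64L, image_width = 64L, n_osteocytes = 2L,
                   osteocyte_axes_range = c(4, 6), connection_probability = 1,
                   connection_radius = 50, dead_end_rate = 0.5,
                   dead_end_length_range = c(5, 10), seed = seed), ...)
}

make_scene <- function(cfg, seed) {
  cfg$seed <- as.integer(seed)
  generate_scene(cfg)
}
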