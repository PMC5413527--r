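# Small, fast phantoms for unit tests. Acceptance tests use the default
# (64 x 64, 24-slice) geometry; unit tests use this reduced field of view.
small_spec <- function(...) {
  args <- list(...)
  defaults <- list(matrix_size = 32, n_slices = 12, edv_ml = 60,
                   ef_true = 0.65, poisson = FALSE, seed = 7L)
  do.call(phantom_spec, utils::modifyList(defaults, args))
}

small_study <- function(...) generate_study(small_spec(...))

# Random gated study (not a phantom) for I/O tests.
random_study <- function(n_frames = 8, n_slices = 3, m = 6, seed = 1) {
  set.seed(seed)
  gated_study(array(sample.int(500, n_frames * n_slices * m * m,
                               replace = TRUE),
                    c(n_frames, n_slices, m, m)),
              pixel_mm = 6.4, slice_mm = 6.4)
}
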