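# Small fixture builders shared across test files. Everything is generated
# in code at test time; sizes are kept small so the whole suite stays fast.

tiny_imbalanced <- function(seed = 11L, n_pd = 18L, n_control = 4L,
                            size = c(24L, 24L), slices = 3L) {
  ds <- generate_singlescanner_imbalanced(
    cohort_spec(n_pd = n_pd, n_control = n_control, slices_per_subject = slices,
                size = size, seed = seed))
  split_subjects(ds, seed = seed)
}

tiny_multiscanner <- function(seed = 12L, n_pd = 10L, n_control = 12L,
                              size = c(24L, 24L), slices = 3L,
                              scanner_null = FALSE) {
  profs <- if (scanner_null) {
    list(ppmi = scanner_profile("ppmi_like"),
         nifd = scanner_profile("ppmi_like",
                                slice_thickness_mm = 3.0,
                                pixel_spacing_mm = c(2.5, 2.5)))
  } else {
    list(ppmi = scanner_profile("ppmi_like"), nifd = scanner_profile("nifd_like"))
  }
  ds <- generate_multiscanner(
    cohort_spec(n_pd = n_pd, n_control = n_control, slices_per_subject = slices,
                size = size, seed = seed),
    profiles = profs, control_ratio = c(1, 2))
  split_subjects(ds, seed = seed)
}

tiny_arch <- function(size = c(24L, 24L), taps = c("fc1", "fc2", "softmax")) {
  dc_architecture("custom", input_shape = size, conv_filters = c(4L, 8L),
                  fc_sizes = c(12L, 8L), taps = taps)
}

fast_control <- function(seed = 1L, epochs = 2L, batch_size = 32L) {
  dccnn_control(batch_size = batch_size, epochs = epochs, base_lr = 1e-4,
                max_lr = 3e-3, half_cycle = 10L, gamma = 0.999, seed = seed)
}
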