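# Small phantom configurations shared across test files. The compact
# geometry keeps per-test runtime low; the full default geometry is
# exercised by the end-to-end recovery tests.

small_spec <- function(...) {
  args <- list(grid_shape = c(48, 48, 48), endo_radius = 8, epi_radius = 14,
               long_axis_extent = 30, noise_sd = 0, misalignment = NULL)
  args <- utils::modifyList(args, list(...), keep.null = TRUE)
  do.call(phantom_spec, args)
}

# 64^3 phantom with lesions breaking the rotational symmetry of the shell
# (needed so all six rigid degrees of freedom are identifiable)
reg_spec <- function(...) {
  args <- list(grid_shape = c(64, 64, 64), endo_radius = 10, epi_radius = 17,
               long_axis_extent = 40, noise_sd = 0, misalignment = NULL,
               lesions = data.frame(segment = c(7, 2), depth_from = 0,
                                    depth_to = 0.6, delta_hu = c(80, 60)))
  args <- utils::modifyList(args, list(...), keep.null = TRUE)
  do.call(phantom_spec, args)
}

dice <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

calcium_spec <- function(grid = c(40, 40, 8), noise_sd = 0, seed = 1) {
  phantom_spec(grid_shape = grid, spacing = c(1, 1, 3),
               lv_center = c((grid[1] - 1) / 2, (grid[2] - 1) / 2,
                             (grid[3] - 1) * 1.5),
               endo_radius = 5, epi_radius = 9, long_axis_extent = 18,
               noise_sd = noise_sd, misalignment = NULL, seed = seed)
}
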