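# Shared fixtures: small, fast phantom configurations built in code.
# Grids are deliberately coarse (24-32 voxels per axis) so each helper call
# stays in the tens of milliseconds; acceptance checks use the full default
# grid instead.

small_params <- function(...) {
  aging_params(grid_dim = 24, voxel_size = 4, ...)
}

mid_params <- function(...) {
  aging_params(grid_dim = 32, voxel_size = 3, ...)
}

# one mid-resolution rendered phantom, memoised across tests
test_phantom <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      p <- mid_params(noise_sd = 0.03)
      cache <<- render_phantom(phantom_spec("fix", 0.47, 0.32, 0.21, 195,
                                            seed = 6, params = p))
    }
    cache
  }
})

# piecewise-constant image from a phantom's true labels
clean_intensity <- function(ph, params = ph$spec$params) {
  means <- params$class_means[c("gm", "wm", "csf", "bg")]
  volume_image(array(means[ph$labels], dim(ph$labels)),
               ph$truth$voxel_size, ph$truth$origin)
}
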