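# Shared fixtures, generated in code. Heavy simulations are memoized so
# several test files can reuse one cohort.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixtures)) assign(key, force(expr), envir = .fixtures)
  get(key, envir = .fixtures)
}

# small noisy cohort at the generator's default SNR, reduced size
small_sim <- function() memo("small_sim", {
  simulate_falff_panel(cohort_config(n_subjects = 8,
                                     grid_dims = c(10L, 10L, 10L),
                                     n_volumes = 64L, seed = 42L))
})

small_fit <- function() memo("small_fit", ort_cva(small_sim()$panel, seed = 42L))

# noise-free cohort: every subject responds, differences exactly planted
noisefree_sim <- function() memo("noisefree_sim", {
  simulate_falff_panel(cohort_config(n_subjects = 6,
                                     grid_dims = c(10L, 10L, 10L),
                                     n_volumes = 64L,
                                     responder_fraction = 1,
                                     noise_sd = 0, seed = 7L),
                       standardize = "none")
})

noisefree_fit <- function() memo("noisefree_fit",
                                 ort_cva(noisefree_sim()$panel, seed = 7L))

# 24-subject noise-free cohort: the identity permutation is effectively
# never redrawn, so the permutation p attains its add-one minimum
noisefree_big <- function() memo("noisefree_big", {
  sim <- simulate_falff_panel(cohort_config(n_subjects = 24,
                                            grid_dims = c(10L, 10L, 10L),
                                            n_volumes = 64L,
                                            responder_fraction = 1,
                                            noise_sd = 0, seed = 12L),
                              standardize = "none")
  list(sim = sim, fit = ort_cva(sim$panel, seed = 12L))
})

# fixed 5 subjects x 2 conditions x 6 voxels panel for exact oracles
tiny_panel <- function() {
  set.seed(11)
  arr <- array(stats::rnorm(5 * 2 * 6), dim = c(5, 2, 6))
  # plant a weak increasing component on the first three voxels
  arr[, 2, 1:3] <- arr[, 2, 1:3] + 0.8
  scan_panel(arr, subject_ids = paste0("P", 1:5),
             condition_labels = c("pre", "post"))
}

# cuboid blob helper for cluster fixtures
put_blob <- function(vol, xr, yr, zr, value) {
  vol[xr, yr, zr] <- value
  vol
}
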