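# Synthetic cohort, atlas and gene-expression generators

test_that("cohort shapes and clinical bookkeeping are correct", {
  cfg <- cohort_config(n_subjects = 4, timepoints = c(0, 6),
                       grid_dims = c(10, 10, 10), n_volumes = 48, seed = 1)
  co <- simulate_cohort(cfg)
  expect_length(co$scans, 8)                       # 4 subjects x 2 timepoints
  expect_identical(dim(co$scans[[1]]), c(10L, 10L, 10L, 48L))
  expect_identical(nrow(co$clinical), 8L)
  expect_true(all(c("hand_tremor", "crst_a", "crst_b", "crst_c",
                    "crst_total") %in% names(co$clinical)))
  expect_true(all(co$clinical[, 3:7] >= 0))        # scores truncated at 0
  expect_identical(dim(co$truth$true_expression), c(4L, 2L))
})

test_that("identical configs give bit-identical cohorts", {
  cfg <- cohort_config(n_subjects = 4, grid_dims = c(10, 10, 10),
                       n_volumes = 48, seed = 9)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$scans, b$scans)
  expect_identical(a$clinical, b$clinical)
  expect_identical(a$truth, b$truth)
})

test_that("series- and panel-level generators share one ground truth", {
  cfg <- cohort_config(n_subjects = 4, grid_dims = c(10, 10, 10),
                       n_volumes = 48, seed = 9)
  co <- simulate_cohort(cfg)
  pan <- simulate_falff_panel(cfg, standardize = "none")
  expect_identical(co$truth$true_expression, pan$truth$true_expression)
  expect_identical(co$clinical, pan$clinical)
  # the panel's maps equal fALFF computed on the stored series
  f <- compute_falff(co$scans[["S01_m0"]], co$mask, tr = cfg$tr)
  expect_equal(pan$panel$data[1, 1, ], f$values[co$mask], tolerance = 1e-12)
})

test_that("noise-free difference maps are exactly proportional to the pattern", {
  sim <- noisefree_sim()
  p <- sim$truth$pattern_map[sim$mask]
  for (s in 1:3) {
    d <- sim$panel$data[s, 2, ] - sim$panel$data[s, 1, ]
    cc <- sum(d * p) / sum(p^2)
    expect_gt(cc, 0)
    expect_lt(max(abs(d - cc * p)), 1e-10)
  }
})

test_that("pattern map is unit norm, masked, and in-mask fALFF is monotone in expression", {
  sim <- noisefree_sim()
  pm <- sim$truth$pattern_map
  expect_equal(sum(pm^2), 1, tolerance = 1e-12)
  expect_true(all(pm[!sim$mask] == 0))
  # expression increases post-op for every subject in a full-responder cohort
  ex <- sim$truth$true_expression
  expect_true(all(ex[, 2] > ex[, 1]))
  # at a strong positive-support voxel, fALFF ordering follows expression
  v <- which.max(sim$truth$pattern_map[sim$mask])
  ord_f <- order(sim$panel$data[, 2, v])
  expect_identical(ord_f, order(ex[, 2]))
})

test_that("config invariants are enforced", {
  expect_error(cohort_config(n_subjects = 1), ">= 2")
  expect_error(cohort_config(responder_fraction = 1.2), "\\[0, 1\\]")
  expect_error(cohort_config(timepoints = c(1, 3)), "baseline")
  expect_error(cohort_config(timepoints = c(0, 3, 3)), "increasing")
  expect_error(cohort_config(grid_dims = c(4, 16, 16)), "too small")
})

test_that("synthetic atlas tiles the mask with contiguous hemispheric regions", {
  at <- make_atlas(c(16, 16, 16), n_regions = 20, seed = 3)
  lab <- at$labels
  expect_true(all(lab[at$mask] %in% 1:20))
  expect_true(all(lab[!at$mask] == 0))
  expect_identical(sort(unique(as.integer(lab[at$mask]))), 1:20)
  expect_true(all(at$regions$n_voxels > 0))
  # contiguity: every region is a single 6-connected component
  for (r in c(1, 7, 20)) {
    cc <- ortcva:::connected_components(lab == r, connectivity = 6)
    expect_identical(max(cc), 1L)
  }
  # no region straddles the first-axis midline
  for (r in 1:20) {
    xs <- which(lab == r, arr.ind = TRUE)[, 1]
    expect_true(all(xs <= 8) || all(xs > 8))
  }
  expect_setequal(unique(at$regions$hemisphere), c("L", "R"))
})

test_that("atlas generation is deterministic and handles degenerate sizes", {
  a <- make_atlas(c(10, 10, 10), n_regions = 12, seed = 5)
  b <- make_atlas(c(10, 10, 10), n_regions = 12, seed = 5)
  expect_identical(a$labels, b$labels)
  msk <- ortcva:::default_mask(c(8L, 8L, 8L))
  nv <- sum(msk)
  single <- make_atlas(c(8, 8, 8), n_regions = nv, seed = 2)
  expect_true(all(single$regions$n_voxels == 1L))
  expect_error(make_atlas(c(8, 8, 8), n_regions = 1), ">= 2")
  expect_error(make_atlas(c(8, 8, 8), n_regions = nv + 1), "exceeds")
})

test_that("gene matrix plants causal genes and matches region count", {
  at <- make_atlas(c(12, 12, 12), n_regions = 30, seed = 4)
  pv <- rnorm(30)
  g0 <- simulate_gene_expression(at, pv, n_genes = 50, n_causal = 5,
                                 gene_noise_sd = 0, seed = 1)
  expect_identical(dim(g0$expression), c(30L, 50L))
  expect_length(g0$causal_gene_ids, 5)
  for (g in g0$causal_gene_ids)
    expect_equal(abs(cor(g0$expression[, g], pv)), 1, tolerance = 1e-10)
  # noise genes are not perfectly coupled
  noise_ids <- setdiff(colnames(g0$expression), g0$causal_gene_ids)
  expect_lt(max(abs(cor(g0$expression[, noise_ids], pv))), 0.999)
  g1 <- simulate_gene_expression(at, pv, n_genes = 20, n_causal = 0, seed = 2)
  expect_length(g1$causal_gene_ids, 0)
  expect_error(simulate_gene_expression(at, pv[-1], n_genes = 10, n_causal = 2),
               "match")
  expect_error(simulate_gene_expression(at, pv, n_genes = 5, n_causal = 6),
               "n_causal")
  # determinism
  g2 <- simulate_gene_expression(at, pv, n_genes = 50, n_causal = 5,
                                 gene_noise_sd = 0, seed = 1)
  expect_identical(g0, g2)
})
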