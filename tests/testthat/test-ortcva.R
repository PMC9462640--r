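# Ordinal-trend covariance pattern derivation and resampling inference

test_that("noise-free cohort recovers the planted pattern exactly", {
  sim <- noisefree_sim()
  fit <- noisefree_fit()
  p <- sim$truth$pattern_map[sim$mask]
  expect_gte(abs(sum(coef(fit) * p)), 0.999)
  expect_identical(fit$violator_count, 0L)
  # condition-mean expression increases along the order (sign convention)
  expect_gt(diff(colMeans(fitted(fit))), 0)
})

test_that("swapping condition labels negates weights and expression changes", {
  sim <- small_sim()
  pan <- sim$panel
  swapped <- scan_panel(pan$data[, 2:1, , drop = FALSE], pan$subject_ids,
                        rev(pan$condition_labels), mask = pan$mask)
  f1 <- ort_cva(pan, seed = 1)
  f2 <- ort_cva(swapped, seed = 1)
  expect_equal(f2$weights, -f1$weights, tolerance = 1e-8)
  # for the same physical scans (original pre/post), expression
  # differences negate; column 2 of the swapped panel is the original pre
  d1 <- fitted(f1)[, 2] - fitted(f1)[, 1]
  d2 <- fitted(f2)[, 1] - fitted(f2)[, 2]
  expect_equal(unname(d2), unname(-d1), tolerance = 1e-8)
})

test_that("violator counting matches its definition, ties included", {
  expect_identical(count_violators(cbind(pre = c(1, 2, 3), post = c(2, 1, 4))), 1L)
  expect_identical(count_violators(cbind(1:4, 2:5)), 0L)
  # 24 subjects, exactly 2 with decreases
  sc <- cbind(rep(0, 24), rep(1, 24))
  sc[c(5, 17), 2] <- -1
  expect_identical(count_violators(sc), 2L)
  # ties count as violations
  expect_identical(count_violators(cbind(c(1, 1), c(1, 2))), 1L)
  # multi-condition: any non-increase anywhere violates
  # rows: (1,2,3) ok, (2,3,3) tie -> violation, (3,4,5) ok
  expect_identical(count_violators(cbind(1:3, 2:4, c(3, 3, 5))), 1L)
  expect_error(count_violators(matrix(1, 3, 1)), "2 ordered conditions")
})

test_that("expression scores equal brute-force projections on a tiny panel", {
  pan <- tiny_panel()
  fit <- ort_cva(pan)
  X <- ortcva:::panel_matrix(pan)
  gm <- colMeans(X)
  w <- coef(fit)
  # independent re-projection, subject by subject
  viol <- 0L
  for (s in 1:5) {
    e_pre <- sum((pan$data[s, 1, ] - gm) * w)
    e_post <- sum((pan$data[s, 2, ] - gm) * w)
    expect_equal(unname(fitted(fit)[s, ]), c(e_pre, e_post), tolerance = 1e-8)
    # expression difference equals the difference-map dot product
    expect_equal(e_post - e_pre,
                 sum((pan$data[s, 2, ] - pan$data[s, 1, ]) * w),
                 tolerance = 1e-8)
    if (e_post <= e_pre) viol <- viol + 1L
  }
  expect_identical(fit$violator_count, viol)
  expect_equal(sum(w^2), 1, tolerance = 1e-12)
})

test_that("the fit is invariant to global positive scaling of the panel", {
  pan <- tiny_panel()
  pan3 <- scan_panel(pan$data * 3, pan$subject_ids, pan$condition_labels)
  f1 <- ort_cva(pan)
  f3 <- ort_cva(pan3)
  expect_equal(f1$weights, f3$weights, tolerance = 1e-8)
  expect_identical(f1$violator_count, f3$violator_count)
  expect_identical(f1$selected_bias, f3$selected_bias)
  p1 <- permutation_test(f1, n_permutations = 100, seed = 5)
  p3 <- permutation_test(f3, n_permutations = 100, seed = 5)
  expect_identical(p1$p, p3$p)
})

test_that("permutation p has add-one bounds and hits the minimum on perfect cohorts", {
  fit <- small_fit()
  pt <- permutation_test(fit, n_permutations = 100, seed = 2)
  expect_gt(pt$p, 0)
  expect_lte(pt$p, 1)
  expect_length(pt$null_distribution, 100)
  expect_true(all(pt$null_distribution >= 0 &
                    pt$null_distribution <= length(fit$subject_ids)))
  # noise-free full-responder cohort: observed statistic beats every draw
  ptn <- permutation_test(noisefree_big()$fit, n_permutations = 199, seed = 3)
  expect_equal(ptn$p, 1 / 200)
})

test_that("bootstrap z-map is infinite on the planted support of a noise-free cohort", {
  sim <- noisefree_sim()
  fit <- noisefree_fit()
  bz <- bootstrap_zmap(fit, n_bootstrap = 100, seed = 4)
  support <- sim$truth$pattern_map[sim$mask] != 0
  expect_true(all(is.infinite(bz$z[support])))
  expect_true(all(bz$z[!support] == 0))
  # thresholding the |z| volume recovers the support exactly
  zv <- bz$zmap
  zv[is.infinite(zv)] <- 1e6
  expect_identical(which(abs(zv) > 1.96), which(sim$truth$pattern_map != 0))
})

test_that("bootstrap z-map is stable in the number of resamplings", {
  fit <- small_fit()
  z1 <- bootstrap_zmap(fit, n_bootstrap = 200, seed = 6)
  z2 <- bootstrap_zmap(fit, n_bootstrap = 400, seed = 6)
  support <- abs(coef(fit)) > quantile(abs(coef(fit)), 0.99)
  rel <- abs(z2$z[support] - z1$z[support]) / abs(z1$z[support])
  expect_lt(median(rel), 0.10)
})

test_that("leave-one-out folds are consistent and highly correlated without noise", {
  fit <- noisefree_fit()
  lo <- loo_validation(fit)
  S <- length(fit$subject_ids)
  expect_identical(dim(lo$patterns), c(length(coef(fit)), S))
  expect_identical(dim(lo$pattern_correlations), c(S, S))
  expect_equal(unname(diag(lo$pattern_correlations)), rep(1, S),
               tolerance = 1e-12)
  off <- lo$pattern_correlations[upper.tri(lo$pattern_correlations)]
  expect_true(all(off >= 0.999))
  expect_identical(nrow(lo$heldout_scores), S * 2L)
})

test_that("leave-one-out fold equals an independent refit on the subsetted panel", {
  sim <- small_sim()
  fit <- small_fit()
  lo <- loo_validation(fit)
  # drop subject 3 by hand and refit from voxel data
  pan <- sim$panel
  sub <- scan_panel(pan$data[-3, , , drop = FALSE], pan$subject_ids[-3],
                    pan$condition_labels, mask = pan$mask)
  ref <- ort_cva(sub, seed = 1)
  w_fold <- lo$patterns[, 3]
  expect_gt(abs(cor(w_fold, coef(ref))), 1 - 1e-6)
  # held-out scores match scoring the held-out scans against the fold fit
  hs <- lo$heldout_scores[lo$heldout_scores$subject_id ==
                            fit$subject_ids[3], "raw_score"]
  man <- sweep(rbind(pan$data[3, 1, ], pan$data[3, 2, ]), 2,
               colMeans(ortcva:::panel_matrix(sub)))
  s_ref <- as.numeric(man %*% (w_fold / sqrt(sum(w_fold^2))))
  expect_equal(hs, s_ref, tolerance = 1e-6)
})

test_that("hemispheric derivation equals derivation on a pre-restricted panel", {
  sim <- small_sim()
  hemis <- split_hemispheres(sim$mask)
  left_panel <- subset_panel(sim$panel, hemis$left)
  sel <- hemis$left[sim$mask]
  manual <- scan_panel(sim$panel$data[, , sel, drop = FALSE],
                       sim$panel$subject_ids, sim$panel$condition_labels,
                       mask = hemis$left)
  f1 <- ort_cva(left_panel, seed = 1)
  f2 <- ort_cva(manual, seed = 1)
  expect_identical(f1$weights, f2$weights)
  expect_identical(f1$violator_count, f2$violator_count)
})

test_that("fit preconditions and degenerate panels are rejected informatively", {
  pan <- tiny_panel()
  expect_error(ort_cva(scan_panel(pan$data[1:3, , , drop = FALSE],
                                  paste0("P", 1:3), c("pre", "post"))),
               "4 subjects")
  expect_error(ort_cva(pan, n_components = 50), "larger than rank")
  expect_error(ort_cva(pan, log_transform = TRUE), "positive")
  const <- scan_panel(array(1, dim = c(5, 2, 12)), paste0("P", 1:5),
                      c("a", "b"))
  expect_error(ort_cva(const), "degenerate")
})
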