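# PLS1 imaging transcriptomics, permutation/bootstrap inference, ORA

make_genes <- function(n_regions = 40, n_genes = 30, seed = 1) {
  set.seed(seed)
  matrix(rnorm(n_regions * n_genes), n_regions, n_genes,
         dimnames = list(NULL, sprintf("gene%04d", seq_len(n_genes))))
}

test_that("a perfect predictor gene dominates PLS1", {
  set.seed(2)
  y <- rnorm(40)
  g <- make_genes(40, 30, seed = 3)
  g[, 12] <- y                                  # causal gene, noise-free
  fit <- fit_pls1(g, y)
  expect_identical(names(which.max(abs(fit$gene_weights))), "gene0012")
  expect_gte(fit$variance_explained, 0.5)
  # with few noise genes over many regions the causal gene carries nearly
  # all the weight (contamination scales as n_genes / n_regions)
  set.seed(23)
  yy <- rnorm(1000)
  gg <- matrix(rnorm(1000 * 5), 1000, 5,
               dimnames = list(NULL, paste0("g", 1:5)))
  gg[, 2] <- yy
  fit2 <- fit_pls1(gg, yy)
  expect_identical(names(which.max(abs(fit2$gene_weights))), "g2")
  expect_gte(fit2$variance_explained, 0.99)
})

test_that("PLS1 scores track the response when it equals the leading gene axis", {
  g <- make_genes(50, 20, seed = 4)
  gs <- scale(g)
  sv <- svd(gs)
  y <- gs %*% sv$v[, 1]
  fit <- fit_pls1(g, as.numeric(y))
  expect_gte(abs(cor(fit$region_scores, y)), 0.99)
})

test_that("PLS1 is invariant to response scaling and per-gene affine maps", {
  g <- make_genes(40, 25, seed = 5)
  set.seed(6); y <- rnorm(40)
  f1 <- fit_pls1(g, y)
  f2 <- fit_pls1(g, 2 * y)
  expect_identical(order(-abs(f1$gene_weights)), order(-abs(f2$gene_weights)))
  expect_equal(f1$variance_explained, f2$variance_explained, tolerance = 1e-12)
  g3 <- sweep(sweep(g, 2, runif(25, 0.5, 2), "*"), 2, rnorm(25), "+")
  f3 <- fit_pls1(g3, y)
  expect_equal(f3$gene_weights, f1$gene_weights, tolerance = 1e-10)
  expect_error(fit_pls1(g[1:5, ], y[1:5]), "10 regions")
  expect_error(fit_pls1(g, rep(1, 40)), "constant response")
})

test_that("PLS1 agrees with an independent PLS implementation", {
  g <- make_genes(45, 20, seed = 7)
  set.seed(8); y <- g[, 3] * 0.8 + rnorm(45, 0, 0.5)
  fit <- fit_pls1(g, y)
  ref <- mixOmics::pls(g, y, ncomp = 1, scale = TRUE, mode = "regression")
  wref <- ref$loadings$X[, 1]
  expect_gt(abs(cor(fit$gene_weights, wref)), 0.999)
  expect_gt(abs(cor(fit$region_scores, ref$variates$X[, 1])), 0.999)
})

test_that("permutation p is add-one bounded and minimal for strong signal", {
  g <- make_genes(40, 20, seed = 9)
  set.seed(10); y <- rnorm(40)
  g[, 5] <- y
  pp <- pls_permutation(g, y, n_perm = 199, seed = 1)
  expect_equal(pp$p, 1 / 200)
  g0 <- make_genes(40, 20, seed = 11)
  pp0 <- pls_permutation(g0, y, n_perm = 100, seed = 2)
  expect_gt(pp0$p, 0)
  expect_lte(pp0$p, 1)
  expect_length(pp0$null, 100)
})

test_that("spin permutation preserves the response multiset and needs coords", {
  g <- make_genes(30, 10, seed = 12)
  set.seed(13)
  y <- rnorm(30)
  coords <- matrix(rnorm(90), 30, 3)
  expect_error(pls_permutation(g, y, method = "spin"), "coordinates")
  sph <- ortcva:::sphere_coords(coords)
  set.seed(14)
  for (i in 1:5) {
    perm <- ortcva:::spin_permutation(sph)
    expect_identical(sort(perm), 1:30)           # a bijection
  }
  pp <- pls_permutation(g, y, n_perm = 100, method = "spin", coords = coords,
                        seed = 3)
  expect_gt(pp$p, 0)
  expect_lte(pp$p, 1)
})

test_that("bootstrap gene ranking recovers planted causal genes", {
  at <- make_atlas(c(12, 12, 12), n_regions = 50, seed = 15)
  set.seed(16)
  pv <- rnorm(50)
  ge <- simulate_gene_expression(at, pv, n_genes = 40, n_causal = 8,
                                 gene_noise_sd = 0.1, seed = 17)
  bw <- bootstrap_gene_weights(ge$expression, pv, n_boot = 200, seed = 18)
  expect_length(bw$ranked_genes, 40)
  expect_identical(anyDuplicated(bw$ranked_genes), 0L)
  ranks <- match(ge$causal_gene_ids, bw$ranked_genes)
  expect_lte(median(ranks), 16)                  # causal genes near the top
  expect_error(bootstrap_gene_weights(ge$expression, pv, n_boot = 50), ">= 100")
})

test_that("null bootstrap z-scores are centred with moderate dispersion", {
  # under a pure null the bootstrap SD conditionally underestimates the
  # sampling SD (draws share ~63% of regions), so z is over-dispersed
  # relative to N(0,1) by a factor ~1.5; it is a ranking statistic
  g <- make_genes(60, 40, seed = 19)
  set.seed(20); y <- rnorm(60)
  bw <- bootstrap_gene_weights(g, y, n_boot = 200, seed = 21)
  expect_lt(abs(median(bw$z)), 0.5)
  expect_gte(mean(abs(bw$z) < 4), 0.9)
  expect_gt(mean(bw$z > 0), 0.3)
  expect_lt(mean(bw$z > 0), 0.7)
})

test_that("ORA matches the exact hypergeometric sum", {
  bg <- sprintf("gene%04d", 1:20)
  sets <- list(hit = bg[1:5], off = sprintf("x%d", 1:4))
  sel <- c(bg[1:4], bg[10])                      # overlap 4 with "hit"
  res <- enrichment_ora(sel, sets, bg)
  p_exact <- (choose(5, 4) * choose(15, 1) + choose(5, 5) * choose(15, 0)) /
    choose(20, 5)
  expect_equal(res$p[res$set == "hit"], p_exact, tolerance = 1e-12)
  expect_identical(res$overlap[res$set == "off"], 0L)
  expect_equal(res$p[res$set == "off"], 1)
  # selection = background: every overlap is the full set, p = 1
  res_all <- enrichment_ora(bg, list(s = bg[3:9]), bg)
  expect_identical(res_all$overlap, 7L)
  expect_equal(res_all$p, 1)
  expect_error(enrichment_ora(character(0), sets, bg), "empty")
  expect_error(enrichment_ora(c(bg[1], "zzz"), sets, bg), "subset")
})

test_that("BH adjustment is monotone and matches the manual formula", {
  bg <- sprintf("g%03d", 1:50)
  set.seed(22)
  sets <- lapply(1:8, function(i) sample(bg, sample(5:15, 1)))
  names(sets) <- paste0("set", 1:8)
  sel <- sample(bg, 12)
  res <- enrichment_ora(sel, sets, bg)
  expect_true(all(diff(res$q[order(res$p)]) >= -1e-12))
  manual <- rev(cummin(rev(sort(res$p) * 8 / seq_len(8))))
  expect_equal(sort(res$q), pmin(manual, 1), tolerance = 1e-12)
})

test_that("GMT files parse into named gene-id lists", {
  gmt <- read_gmt(system.file("extdata", "example_sets.gmt",
                              package = "ortcva"))
  expect_setequal(names(gmt),
                  c("motor_program", "cerebellar_signalling", "housekeeping"))
  expect_identical(gmt$motor_program,
                   c("gene0001", "gene0002", "gene0003", "gene0004", "gene0005"))
})
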