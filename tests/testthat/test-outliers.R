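test_that("spatial covariates reproduce simple geometries", {
  # samples on a line: axis 1 recovers position up to affine transform
  n <- 12
  geno <- matrix(rbinom(n * 20, 2, 0.5), n, 20)
  gm <- make_gm(geno, x = seq(0, 1100, length.out = n), y = rep(0, n))
  pc <- spatial_covariates(gm, k = 3)
  expect_equal(abs(cor(pc[, 1], gm$meta$x)), 1, tolerance = 1e-9)
  expect_lt(stats::sd(pc[, 2]), 1e-4)     # no variance off the line
  expect_lt(stats::sd(pc[, 3]), 1e-4)
  # 4-point unit square: eigenvalues of the double-centred squared-distance
  # matrix, by hand
  gm_sq <- make_gm(geno[1:4, ], x = c(0, 1, 1, 0), y = c(0, 0, 1, 1))
  pc_sq <- spatial_covariates(gm_sq, k = 2)
  D2 <- as.matrix(stats::dist(cbind(gm_sq$meta$x, gm_sq$meta$y)))^2
  J <- diag(4) - 1 / 4
  B <- -0.5 * J %*% D2 %*% J
  ev <- sort(eigen(B, symmetric = TRUE)$values, decreasing = TRUE)
  expect_equal(unname(sort(colSums(pc_sq^2), decreasing = TRUE)), ev[1:2],
               tolerance = 1e-9)
  gm_bad <- make_gm(geno, x = rep(1, n), y = rep(1, n))
  expect_error(spatial_covariates(gm_bad), "degenerate")
})

test_that("RDA scan flags a perfectly associated locus and nests thresholds", {
  set.seed(51)
  sim <- sim_outlier_gm(n_sites = 6, n_per_group = 10, n_loci = 120, n_out = 0)
  gm <- sim$gm
  # overwrite one locus with the exact ecotope contrast
  gm$geno[, 5] <- ifelse(gm$meta$ecotope == "domestic", 2L, 0L)
  res <- rda_scan(gm, spatial_covariates(gm), n_perm = 199, seed = 1)
  expect_equal(which.max(abs(res$z)), 5L, ignore_attr = TRUE)
  expect_gt(abs(res$z[5]), 3)
  expect_true(all(which(res$flag_3sd) %in% which(res$flag_2sd)))
  expect_lt(res$p, 0.05)
  expect_equal(mean(res$z), 0, tolerance = 1e-10)
  expect_equal(stats::sd(res$z), 1, tolerance = 1e-10)
})

test_that("RDA constrained axis matches vegan's partial RDA", {
  skip_if_not_installed("vegan")
  set.seed(52)
  sim <- sim_outlier_gm(n_sites = 5, n_per_group = 8, n_loci = 60, n_out = 3,
                        delta = 1.5)
  gm <- sim$gm
  covs <- spatial_covariates(gm, k = 2)
  res <- rda_scan(gm, covs, n_perm = 99, seed = 1)
  G <- scale(gm$geno, scale = FALSE)
  G[is.na(G)] <- 0
  eco <- as.numeric(gm$meta$ecotope == "domestic")
  vg <- vegan::rda(G ~ eco + Condition(covs))
  v_load <- vegan::scores(vg, display = "species", choices = 1,
                          scaling = 0)[, 1]
  # loadings agree up to sign and scale
  expect_gt(abs(cor(res$loadings, v_load)), 1 - 1e-6)
  # constrained variance fraction agrees
  v_frac <- vg$CCA$tot.chi / (vg$CCA$tot.chi + vg$CA$tot.chi)
  expect_equal(res$variance_explained, v_frac, tolerance = 1e-6)
})

test_that("outflank-style scan gates on heterozygosity and finds strong shifts", {
  set.seed(53)
  sim <- sim_outlier_gm(n_sites = 20, n_per_group = 5, n_loci = 400,
                        n_out = 5, fst = 0.1, delta = 2)
  res <- outflank_scan(sim$gm, "ecotope")
  low_he <- res$table$he < 0.1
  expect_true(!any(res$table$flag[low_he]))
  expect_true(all(is.na(res$table$p[low_he])))
  expect_true(res$df > 0 && res$mean_fst > 0)
  # strong injected loci are mostly recovered
  hits <- sum(sim$outliers %in% res$table$locus[res$table$flag])
  expect_gte(hits, 3)
})

test_that("fsthet-style envelope is valid and flags fixed differences", {
  set.seed(54)
  sim <- sim_outlier_gm(n_sites = 8, n_per_group = 8, n_loci = 300, n_out = 0)
  gm <- sim$gm
  gm$geno[, 7] <- ifelse(gm$meta$ecotope == "domestic", 2L, 0L)
  res <- fsthet_scan(gm, "ecotope")
  expect_true(all(res$envelope$upper >= res$envelope$lower - 1e-12))
  expect_true(res$table$flag[7])
  # flag fraction near alpha on the remaining neutral loci
  expect_lt(mean(res$table$flag[-7]), 0.15)
})

test_that("random forest ranks a perfect classifier locus first", {
  set.seed(55)
  sim <- sim_outlier_gm(n_sites = 5, n_per_group = 8, n_loci = 40, n_out = 0)
  gm <- sim$gm
  gm$geno[, 3] <- ifelse(gm$meta$ecotope == "domestic", 2L, 0L)
  res <- rf_rank(gm, spatial_covs = NULL, n_trees = 500,
                 spatial_correction = "off", seed = 2)
  expect_equal(names(which.max(res$importance)), colnames(gm$geno)[3])
  expect_true(colnames(gm$geno)[3] %in% res$ranked_loci)
  expect_gt(res$importance[3], res$threshold)
  expect_true(res$converged)
  expect_error(rf_rank(subset_genotypes(gm, gm$meta$ecotope == "wild")),
               "ecotopes")
})

test_that("backwards purging keeps the informative locus and obeys the loop contract", {
  set.seed(56)
  sim <- sim_outlier_gm(n_sites = 5, n_per_group = 8, n_loci = 30, n_out = 0)
  gm <- sim$gm
  gm$geno[, 1] <- ifelse(gm$meta$ecotope == "domestic", 2L, 0L)
  ranked <- colnames(gm$geno)[1:10]
  res <- rf_backwards_purge(gm, ranked, n_trees = 300, seed = 3)
  expect_true(colnames(gm$geno)[1] %in% res$best_loci)
  expect_lt(res$best_oob_er, 0.1)
  expect_equal(nrow(res$trajectory), length(ranked) - 1)
  expect_equal(res$trajectory$n_loci, seq(length(ranked), 2))
  expect_error(rf_backwards_purge(gm, ranked[1:2]), "at least 3")
})

test_that("consensus sets are exact set operations", {
  f1 <- c(a = TRUE, b = TRUE, c = FALSE, d = FALSE)
  f2 <- c(a = TRUE, b = FALSE, c = TRUE, d = FALSE)
  f3 <- c(a = TRUE, b = TRUE, c = FALSE, d = FALSE)
  cons <- consensus(m1 = f1, m2 = f2, m3 = f3)
  expect_equal(cons$all_methods, "a")
  expect_equal(sort(cons$at_least_2), c("a", "b"))
  expect_equal(unname(cons$method_count[c("a", "b", "c", "d")]), c(3, 2, 1, 0))
  # disjoint sets: empty intersection
  cons2 <- consensus(m1 = c(a = TRUE, b = FALSE), m2 = c(a = FALSE, b = TRUE))
  expect_length(cons2$all_methods, 0)
  expect_error(consensus(m1 = f1, m2 = f2[1:3]), "mismatch")
})

test_that("scan flags are invariant to sample and locus order", {
  set.seed(57)
  sim <- sim_outlier_gm(n_sites = 6, n_per_group = 6, n_loci = 100, n_out = 3,
                        delta = 2)
  gm <- sim$gm
  sperm <- sample(nrow(gm$geno)); lperm <- sample(ncol(gm$geno))
  gm_p <- subset_genotypes(gm, sperm, lperm)
  of1 <- outflank_scan(gm, "ecotope")
  of2 <- outflank_scan(gm_p, "ecotope")
  expect_equal(of1$table$flag[match(of2$table$locus, of1$table$locus)],
               of2$table$flag)
  fh1 <- fsthet_scan(gm, "ecotope")
  fh2 <- fsthet_scan(gm_p, "ecotope")
  expect_equal(fh1$table$flag[match(fh2$table$locus, fh1$table$locus)],
               fh2$table$flag)
})
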