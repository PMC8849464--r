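test_that("elevation field is deterministic and degenerates at long range", {
  f1 <- generate_elevation_field(c(40, 40), 100, 2000, seed = 9)
  f2 <- generate_elevation_field(c(40, 40), 100, 2000, seed = 9)
  expect_identical(f1$values, f2$values)
  f3 <- generate_elevation_field(c(40, 40), 100, 2000, seed = 10)
  expect_false(identical(f1$values, f3$values))
  # range -> infinity: spatially constant
  fc <- generate_elevation_field(c(40, 40), 100, 1e12, seed = 9)
  expect_lt(stats::sd(fc$values), 0.1 * stats::sd(f1$values))
  expect_true(all(f1$values >= 0 & f1$values <= 3000))
  expect_error(generate_elevation_field(c(0, 10), 100, 100), "dimensions")
})

test_that("empirical variogram range matches the generating range", {
  # Monte-Carlo variogram oracle: ensemble covariance (no demeaning) at a set
  # of lags, range fitted by least squares on log covariance
  lags <- c(2, 4, 6, 8, 12, 16)
  covs <- matrix(0, 8, length(lags))
  for (i in 1:8) {
    f <- generate_elevation_field(c(100, 100), 1, 10, seed = 100 + i)
    v <- (f$values - 1500) / 500
    covs[i, ] <- vapply(lags, function(k)
      mean(v[, 1:(100 - k)] * v[, (k + 1):100]), numeric(1))
  }
  cbar <- colMeans(covs)
  expect_true(all(cbar > 0))
  fitted_range <- -1 / stats::coef(stats::lm(log(cbar) ~ lags))[[2]]
  expect_lt(abs(fitted_range - 10) / 10, 0.3)
})

test_that("site placement respects separation, ecotope design and errors", {
  r <- raster_surface(matrix(0, 30, 30), cell_size = 100)
  s <- place_sites(r, 25, min_separation = 300, n_dual = 7, seed = 3)
  expect_equal(nrow(s), 25)
  expect_gte(min(stats::dist(s[, c("x", "y")])), 300)
  expect_equal(sum(s$has_domestic & s$has_wild), 7)
  expect_true(all(s$has_domestic | s$has_wild))
  # forced placement on a 2-cell raster
  r2 <- raster_surface(matrix(0, 1, 2), cell_size = 1)
  s2 <- place_sites(r2, 2, min_separation = 1, seed = 1)
  expect_equal(sort(s2$col), c(1, 2))
  # infeasible separation
  expect_error(place_sites(r, 3, min_separation = 1e6, seed = 1),
               "placement error")
})

test_that("simulated genotypes are valid, deterministic and resistance-structured", {
  cfg <- sim_config(n_sites = 12, samples_per_site = 8, n_loci = 300,
                    n_dual_sites = 4, grid_shape = c(40, 40),
                    missing_rate = 0.05, seed = 21)
  d1 <- simulate_landscape_dataset(cfg)
  d2 <- simulate_landscape_dataset(cfg)
  expect_identical(d1$gm$geno, d2$gm$geno)
  expect_true(all(is.na(d1$gm$geno) | d1$gm$geno %in% 0:2))
  expect_true(all(d1$truth$site_frequencies >= 0 &
                    d1$truth$site_frequencies <= 1))
  expect_equal(length(d1$truth$outlier_locus_ids), cfg$n_outlier_loci)
  miss <- mean(is.na(d1$gm$geno))
  expect_lt(abs(miss - 0.05), 0.01)
  # covariance monotonicity: between-site frequency correlation non-increasing
  # in effective distance (binned pairs)
  fr <- d1$truth$site_frequencies
  site_of <- sub(":.*", "", rownames(fr))
  sel <- !duplicated(site_of)       # one group per site
  fr <- fr[sel, ]
  z <- stats::qnorm(pmin(pmax(fr, 1e-9), 1 - 1e-9))
  cc <- stats::cor(t(z))
  dd <- unclass(d1$truth$true_effective_dm)[site_of[sel], site_of[sel]]
  ltc <- cc[lower.tri(cc)]; ltd <- dd[lower.tri(dd)]
  bins <- cut(ltd, stats::quantile(ltd, seq(0, 1, 0.25)),
              include.lowest = TRUE)
  means <- tapply(ltc, bins, mean)
  expect_true(all(diff(means) <= 0.1))   # non-increasing up to noise
  expect_gt(means[1], means[4])
})

test_that("baseline F is recovered as multilocus Weir-Cockerham FST", {
  # direct-simulation oracle: independent brute-force frequency simulator at
  # the same F-model settings, no spatial correlation in either
  set.seed(5)
  reps_pkg <- replicate(10, {
    sim <- sim_outlier_gm(n_sites = 25, n_per_group = 5, n_loci = 200,
                          n_out = 0, fst = 0.1)
    wc_theta(sim$gm, "site")$theta
  })
  reps_oracle <- replicate(10, {
    p0 <- stats::rbeta(200, 2, 2)
    geno <- NULL; pop <- character(0)
    for (s in 1:25) {
      p <- stats::rbeta(200, p0 * 9, (1 - p0) * 9)  # (1-F)/F = 9 at F = 0.1
      geno <- rbind(geno, matrix(stats::rbinom(10 * 200, 2, rep(p, each = 10)),
                                 10, 200))
      pop <- c(pop, rep(paste0("S", s), 10))
    }
    oracle_wc_theta(geno, pop)
  })
  expect_lt(abs(mean(reps_pkg) - 0.1), 0.02)
  expect_lt(abs(mean(reps_pkg) - mean(reps_oracle)), 0.02)
})

test_that("configuration invariants are enforced", {
  expect_error(sim_config(n_loci = 10, n_outlier_loci = 10), "n_outlier_loci")
  expect_error(sim_config(baseline_fst = 1.2), "baseline_fst")
  expect_error(sim_config(missing_rate = 1), "missing_rate")
  expect_error(sim_config(n_sites = 200, grid_shape = c(10, 10)), "grid")
})
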