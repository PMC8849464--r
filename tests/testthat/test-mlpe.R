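test_that("MLPE likelihood matches a dense multivariate-normal oracle", {
  set.seed(31)
  d <- sim_mlpe_pairs(10, beta = 0.7, alpha = 2, s2u = 0.5, s2e = 1,
                      x_range = c(-2, 2))
  fit <- mlpe(gdist ~ xdist, d)
  ll <- oracle_mlpe_loglik(fit$y, fit$W, fit$Z, fit$coefficients,
                           fit$sigma2_e, fit$sigma2_u)
  expect_equal(fit$logLik, ll, tolerance = 1e-10)
  expect_true(fit$rho >= 0 && fit$rho < 0.5)
  expect_gt(fit$sigma2_e, 0)
})

test_that("MLPE reduces to OLS when pair noise is independent", {
  set.seed(32)
  d <- sim_mlpe_pairs(12, beta = 0.5, alpha = 1, s2u = 0, s2e = 1,
                      x_range = c(-3, 3))
  fit <- mlpe(gdist ~ xdist, d)
  ols <- stats::coef(stats::lm(gdist ~ xdist, d))
  expect_lt(max(abs(stats::coef(fit) - ols)), 1e-6)
  expect_lt(fit$rho, 1e-6)
  # at rho = 0 the MLPE likelihood equals the iid Gaussian likelihood
  s2 <- mean(stats::resid(stats::lm(gdist ~ xdist, d))^2)
  ll_iid <- sum(stats::dnorm(d$gdist,
                             ols[1] + ols[2] * d$xdist, sqrt(s2), log = TRUE))
  expect_equal(fit$logLik, ll_iid, tolerance = 1e-4)
})

test_that("adding a constant to the predictor moves only the intercept", {
  set.seed(33)
  d <- sim_mlpe_pairs(8, beta = 0.4, s2u = 0.2, s2e = 0.5, x_range = c(0, 10))
  f1 <- mlpe(gdist ~ xdist, d)
  d2 <- d; d2$xdist <- d2$xdist + 1000
  f2 <- mlpe(gdist ~ xdist, d2)
  expect_equal(stats::coef(f1)[["xdist"]], stats::coef(f2)[["xdist"]],
               tolerance = 1e-10)
  expect_equal(stats::coef(f2)[["(Intercept)"]],
               stats::coef(f1)[["(Intercept)"]] - 1000 * stats::coef(f1)[["xdist"]],
               tolerance = 1e-6)
})

test_that("mlpe methods behave: fitted, residuals, predict, simulate, anova", {
  set.seed(34)
  d <- sim_mlpe_pairs(8, beta = 1, s2u = 0.1, s2e = 0.3, x_range = c(-1, 1))
  d$ecotope <- factor(rep(c("domestic", "wild"), length.out = nrow(d)))
  fit <- mlpe(gdist ~ xdist, d)
  expect_equal(fit$fitted + fit$residuals, d$gdist, tolerance = 1e-12)
  expect_equal(predict(fit, d), fit$fitted, tolerance = 1e-12)
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_equal(dim(sims), c(nrow(d), 3L))
  full <- mlpe(gdist ~ xdist * ecotope, d)
  cmp <- anova(fit, full)
  expect_equal(cmp$df[2], 2)
  expect_true(cmp$p[2] >= 0 && cmp$p[2] <= 1)
  s <- summary(full)
  expect_true(all(c("Estimate", "Std. Error") %in% colnames(s$coefficients)))
})

test_that("slope contrast detects a simulated ecotope slope difference", {
  set.seed(35)
  detected <- 0; sign_ok <- 0; n_rep <- 20
  for (r in seq_len(n_rep)) {
    # two strata with slopes differing by 0.002
    d1 <- sim_mlpe_pairs(12, beta = 0.001, alpha = 0.1,
                         s2u = 2e-6, s2e = 2e-5)
    d1$ecotope <- "domestic"
    d2 <- sim_mlpe_pairs(12, beta = 0.003, alpha = 0.1,
                         s2u = 2e-6, s2e = 2e-5)
    d2$pop1 <- paste0("w", d2$pop1); d2$pop2 <- paste0("w", d2$pop2)
    d2$ecotope <- "wild"
    d <- rbind(d1, d2); d$ecotope <- factor(d$ecotope)
    fit <- mlpe(gdist ~ xdist * ecotope, d)
    ct <- slope_contrast(fit)
    if (ct$p_wald < 0.05) {
      detected <- detected + 1
      if (ct$delta_beta > 0) sign_ok <- sign_ok + 1
    }
  }
  expect_gte(detected / n_rep, 0.8)
  expect_gte(sign_ok / max(detected, 1), 0.95)
})

test_that("geographic distances are Euclidean kilometres", {
  s <- data.frame(site_id = c("a", "b", "c"), x = c(0, 3000, 0),
                  y = c(0, 0, 4000))
  d <- geographic_distances(s)
  expect_equal(d["a", "b"], 3)
  expect_equal(d["a", "c"], 4)
  expect_equal(d["b", "c"], 5)
  s$x[2] <- NA
  expect_error(geographic_distances(s), "missing")
})

test_that("mantel test matches exhaustive enumeration and vegan", {
  set.seed(36)
  m1 <- matrix(runif(16), 4); m1 <- m1 + t(m1); diag(m1) <- 0
  m2 <- matrix(runif(16), 4); m2 <- m2 + t(m2); diag(m2) <- 0
  a <- dist_matrix(m1, letters[1:4]); b <- dist_matrix(m2, letters[1:4])
  res <- mantel_test(a, b, n_perm = 50000, seed = 2)
  # exhaustive oracle over all 4! row/column permutations
  perms <- expand.grid(rep(list(1:4), 4))
  perms <- perms[apply(perms, 1, function(p) length(unique(p)) == 4), ]
  r_obs <- cor(m1[lower.tri(m1)], m2[lower.tri(m2)])
  r_all <- apply(perms, 1, function(p)
    cor(m1[lower.tri(m1)], m2[p, p][lower.tri(m2)]))
  p_exact <- mean(r_all >= r_obs - 1e-12)
  expect_lt(abs(res$p - p_exact), 0.02)
  # identity gives r_m = 1
  expect_equal(mantel_test(a, a, n_perm = 99)$r_m, 1)
  # vegan agreement on the statistic
  skip_if_not_installed("vegan")
  vg <- vegan::mantel(stats::as.dist(m1), stats::as.dist(m2),
                      permutations = 99)
  expect_equal(res$r_m, unname(vg$statistic), tolerance = 1e-12)
})

test_that("simulated isolation-by-distance yields positive significant mantel r", {
  set.seed(37)
  ok <- 0
  for (r in 1:20) {
    xy <- matrix(runif(20, 0, 100), 10, 2)
    geo <- as.matrix(stats::dist(xy))
    gen <- 0.01 + 0.002 * geo + matrix(stats::rnorm(100, 0, 0.02), 10)
    gen <- (gen + t(gen)) / 2; diag(gen) <- 0
    res <- mantel_test(dist_matrix(gen), dist_matrix(geo), n_perm = 199,
                       seed = r)
    if (res$r_m > 0 && res$p < 0.05) ok <- ok + 1
  }
  expect_gte(ok / 20, 0.95)
})

test_that("pair tables centre predictors and respect strata", {
  m <- matrix(c(0, 1, 2, 1, 0, 3, 2, 3, 0), 3)
  g <- dist_matrix(m, c("A", "B", "C"))
  x <- dist_matrix(2 * m, c("A", "B", "C"))
  pt <- pair_table(g, x)
  expect_equal(nrow(pt), 3)
  expect_equal(mean(pt$xdist), 0, tolerance = 1e-12)
  strata <- c(A = "domestic", B = "domestic", C = "wild")
  pt2 <- pair_table(g, x, strata = strata)
  expect_equal(nrow(pt2), 1)            # only the A-B within-stratum pair
  expect_equal(as.character(pt2$ecotope), "domestic")
})
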