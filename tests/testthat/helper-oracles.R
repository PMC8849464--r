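# Independent oracles used across the suite. These are deliberately naive
# (loops, enumeration, dense algebra) and share no code with the package
# internals they check.

# genotype_matrix fixture from a plain genotype matrix
make_gm <- function(geno, site = rep("A", nrow(geno)),
                    ecotope = rep(c("domestic", "wild"), length.out = nrow(geno)),
                    x = NULL, y = NULL, year = 2015L) {
  n <- nrow(geno)
  if (is.null(x)) x <- as.numeric(match(site, unique(site))) * 1000
  if (is.null(y)) y <- rep(0, n)
  genotype_matrix(geno, data.frame(
    sample_id = sprintf("s%03d", seq_len(n)), site_id = site,
    ecotope = ecotope, year = year, x = x, y = y))
}

# brute-force Weir-Cockerham multilocus theta (textbook a/b/c formulas)
oracle_wc_theta <- function(geno, pop) {
  num <- den <- 0
  for (l in seq_len(ncol(geno))) {
    g <- geno[, l]; ok <- !is.na(g)
    gl <- g[ok]; pl <- pop[ok]
    ni <- tapply(gl, pl, length)
    pi <- tapply(gl, pl, function(x) sum(x) / (2 * length(x)))
    hi <- tapply(gl, pl, function(x) mean(x == 1))
    r <- length(ni)
    nbar <- mean(ni)
    nc <- (r * nbar - sum(ni^2) / (r * nbar)) / (r - 1)
    pbar <- sum(ni * pi) / (r * nbar)
    s2 <- sum(ni * (pi - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(ni * hi) / (r * nbar)
    a <- (nbar / nc) *
      (s2 - (1 / (nbar - 1)) * (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4))
    b <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
    cc <- hbar / 2
    num <- num + a; den <- den + a + b + cc
  }
  num / den
}

# hand evaluation of the Nei/Chesser-corrected differentiation statistics for
# two groups at one locus, from genotype vectors
oracle_two_group_stats <- function(ga, gb) {
  n <- c(length(ga), length(gb))
  p <- c(sum(ga) / (2 * n[1]), sum(gb) / (2 * n[2]))
  ho <- mean(c(mean(ga == 1), mean(gb == 1)))
  hs_raw <- mean(2 * p * (1 - p))
  nh <- 2 / (1 / n[1] + 1 / n[2])
  hs <- (nh / (nh - 1)) * (hs_raw - ho / (2 * nh))
  pbar <- mean(p)
  ht <- 2 * pbar * (1 - pbar) + hs / (2 * nh * 2)
  ht_max <- 1 - (sum(p^2) + sum((1 - p)^2)) / 4 + hs / (2 * nh * 2)
  gst <- (ht - hs) / ht
  list(fst_nei = gst,
       gst_hedrick = 2 * (ht - hs) / ((2 * ht - hs) * (1 - hs)),
       fst_meirmans = gst / ((ht_max - hs) / ht_max))
}

# dense multivariate-normal log density for the MLPE covariance
oracle_mlpe_loglik <- function(y, X, Z, theta, s2e, s2u) {
  m <- length(y)
  Sigma <- s2e * diag(m) + s2u * tcrossprod(Z)
  r <- y - as.numeric(X %*% theta)
  as.numeric(-0.5 * (m * log(2 * pi) +
                       determinant(Sigma, logarithm = TRUE)$modulus +
                       t(r) %*% solve(Sigma, r)))
}

# simulate MLPE pair data over all pairs of n_pop populations
sim_mlpe_pairs <- function(n_pop, beta = 0.002, alpha = 0.1, s2u = 1e-6,
                           s2e = 4e-6, x_range = c(0, 100)) {
  pr <- t(utils::combn(n_pop, 2))
  m <- nrow(pr)
  Z <- matrix(0, m, n_pop)
  Z[cbind(seq_len(m), pr[, 1])] <- 1
  Z[cbind(seq_len(m), pr[, 2])] <- 1
  x <- stats::runif(m, x_range[1], x_range[2])
  u <- stats::rnorm(n_pop, 0, sqrt(s2u))
  y <- alpha + beta * (x - mean(x)) + as.numeric(Z %*% u) +
    stats::rnorm(m, 0, sqrt(s2e))
  data.frame(pop1 = paste0("p", pr[, 1]), pop2 = paste0("p", pr[, 2]),
             xdist = x - mean(x), gdist = y)
}

# two-ecotope genotype fixture with injected outlier loci: n_sites demes at
# baseline differentiation fst, outlier loci shifted by delta (logit) in the
# domestic groups
sim_outlier_gm <- function(n_sites = 20, n_per_group = 5, n_loci = 200,
                           n_out = 5, fst = 0.1, delta = 2) {
  p0 <- stats::rbeta(n_loci, 2, 2)
  a <- p0 * (1 - fst) / fst
  b <- (1 - p0) * (1 - fst) / fst
  out_idx <- if (n_out > 0) seq_len(n_out) else integer(0)
  geno <- NULL; site <- character(0); eco <- character(0)
  for (s in seq_len(n_sites)) {
    p <- stats::rbeta(n_loci, a, b)
    for (e in c("domestic", "wild")) {
      pe <- p
      if (e == "domestic" && length(out_idx)) {
        pe[out_idx] <- stats::plogis(stats::qlogis(
          pmin(pmax(p[out_idx], 1e-9), 1 - 1e-9)) + delta)
      }
      gblock <- matrix(stats::rbinom(n_per_group * n_loci, 2,
                                     rep(pe, each = n_per_group)),
                       n_per_group, n_loci)
      geno <- rbind(geno, gblock)
      site <- c(site, rep(paste0("S", s), n_per_group))
      eco <- c(eco, rep(e, n_per_group))
    }
  }
  colnames(geno) <- sprintf("L%04d", seq_len(n_loci))
  gm <- make_gm(geno, site = site, ecotope = eco,
                x = as.numeric(factor(site)) * 1000 + stats::rnorm(length(site)),
                y = stats::rnorm(length(site)))
  list(gm = gm, outliers = colnames(geno)[out_idx])
}
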