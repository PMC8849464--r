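#' Spatial covariates from principal coordinates of geographic distance
#'
#' First `k` axes of classical multidimensional scaling (principal
#' coordinates) of the inter-sample geographic distance matrix; used to
#' condition the association scans on spatial population structure.
#'
#' @param gm a `genotype_matrix`.
#' @param k number of axes (default 3).
#' @return numeric matrix, samples x k.
#' @export
spatial_covariates <- function(gm, k = 3) {
  xy <- cbind(gm$meta$x, gm$meta$y)
  if (nrow(unique(xy)) < 2) stop("degenerate coordinates: all samples coincide")
  if (nrow(xy) < k + 1) stop("need at least k + 1 samples")
  d <- stats::dist(xy)
  pc <- stats::cmdscale(d, k = k)
  if (ncol(pc) < k) {
    # degenerate geometry (e.g. collinear points): pad with zero axes
    pc <- cbind(pc, matrix(0, nrow(pc), k - ncol(pc)))
  }
  colnames(pc) <- paste0("PCo", seq_len(k))
  rownames(pc) <- rownames(gm$geno)
  pc
}

## centre genotypes per locus and fill missing calls with the locus mean;
## multivariate scans need a complete matrix
centred_genotypes <- function(gm) {
  g <- gm$geno
  mu <- colMeans(g, na.rm = TRUE)
  gc <- sweep(g, 2, mu)
  gc[is.na(gc)] <- 0
  gc
}

## residualise the columns of m on covariates (with intercept)
residualise <- function(m, covs) {
  X <- cbind(1, covs)
  qr_x <- qr(X)
  m - qr.fitted(qr_x, m)
}

#' Rank loci by random-forest importance for ecotope classification
#'
#' Runs several independent random forests classifying domestic vs wild from
#' genotypes (optionally residualised on spatial covariates), with
#' balanced-class subsampling per tree. Importance is the scaled permutation
#' importance (mean decrease in accuracy / SD); per-locus importances are
#' averaged over runs and the pairwise Pearson correlation of importances
#' across runs is reported as a convergence check.
#'
#' @param gm a `genotype_matrix` (both ecotopes present).
#' @param spatial_covs covariates from [spatial_covariates()], or `NULL`.
#' @param n_trees trees per forest (default 5000; raise towards 1e5 for
#'   production runs).
#' @param n_runs independent forests (default 3).
#' @param threshold mean scaled importance above which a locus is retained.
#' @param spatial_correction `"residualise"`, `"covariates"` (add the axes as
#'   predictors) or `"off"`.
#' @param min_convergence warn and flag if mean inter-run correlation of
#'   importances falls below this (default 0.5).
#' @param seed integer seed.
#' @return list with `importance` (per-locus mean), `per_run`, `ranked_loci`
#'   (above threshold, sorted), `run_correlations`, `converged`, `oob_er`.
#' @export
rf_rank <- function(gm, spatial_covs = NULL, n_trees = 5000, n_runs = 3,
                    threshold = 3,
                    spatial_correction = c("residualise", "covariates", "off"),
                    min_convergence = 0.5, seed = 1L) {
  spatial_correction <- match.arg(spatial_correction)
  y <- factor(gm$meta$ecotope, levels = c("domestic", "wild"))
  if (length(unique(y)) < 2) stop("both ecotopes must be present")
  if (ncol(gm$geno) < 10) stop("need at least 10 loci")
  X <- centred_genotypes(gm)
  if (spatial_correction == "residualise" && !is.null(spatial_covs)) {
    X <- residualise(X, spatial_covs)
  } else if (spatial_correction == "covariates" && !is.null(spatial_covs)) {
    X <- cbind(X, spatial_covs)
  }
  n_min <- min(table(y))
  imp <- matrix(NA_real_, ncol(X), n_runs,
                dimnames = list(colnames(X), NULL))
  oob <- numeric(n_runs)
  for (r in seq_len(n_runs)) {
    fit <- with_seed(substream_seed(seed, 100L + r), {
      randomForest::randomForest(
        x = X, y = y, ntree = n_trees, importance = TRUE,
        strata = y, sampsize = c(n_min, n_min))
    })
    imp[, r] <- randomForest::importance(fit, type = 1, scale = TRUE)[, 1]
    oob[r] <- fit$err.rate[n_trees, "OOB"]
  }
  imp <- imp[colnames(gm$geno), , drop = FALSE]  # drop covariate rows if any
  run_cor <- stats::cor(imp)
  mean_cor <- mean(run_cor[lower.tri(run_cor)])
  converged <- is.na(mean_cor) || mean_cor >= min_convergence
  if (!converged) {
    warning(sprintf(
      "random-forest runs did not converge (mean importance correlation %.2f < %.2f); increase n_trees",
      mean_cor, min_convergence))
  }
  mean_imp <- rowMeans(imp)
  ranked <- names(sort(mean_imp[mean_imp > threshold], decreasing = TRUE))
  list(importance = mean_imp, per_run = imp, ranked_loci = ranked,
       run_correlations = run_cor, converged = converged,
       oob_er = mean(oob), threshold = threshold)
}

#' Backwards purging of ranked loci by out-of-bag error
#'
#' Starting from the ranked locus set, repeatedly fits a random forest,
#' records the out-of-bag error rate (OOB-ER), and discards the least
#' important locus, down to two loci. Returns the subset minimising OOB-ER
#' (ties broken towards the smaller subset).
#'
#' @param gm a `genotype_matrix`.
#' @param ranked_loci character vector of locus ids (>= 3).
#' @param spatial_covs,spatial_correction as in [rf_rank()].
#' @param n_trees trees per iteration (default 2000).
#' @param seed integer seed.
#' @return list with `best_loci`, `best_oob_er`, `trajectory` (data.frame
#'   `n_loci`, `oob_er`, one row per subset from `|ranked|` down to 2).
#' @export
rf_backwards_purge <- function(gm, ranked_loci, spatial_covs = NULL,
                               spatial_correction = "residualise",
                               n_trees = 2000, seed = 1L) {
  if (length(ranked_loci) < 3) stop("need at least 3 ranked loci to purge")
  y <- factor(gm$meta$ecotope, levels = c("domestic", "wild"))
  X_all <- centred_genotypes(gm)
  if (spatial_correction == "residualise" && !is.null(spatial_covs)) {
    X_all <- residualise(X_all, spatial_covs)
  }
  n_min <- min(table(y))
  current <- ranked_loci
  sizes <- integer(0); errs <- numeric(0); subsets <- list()
  it <- 0L
  while (length(current) >= 2) {
    it <- it + 1L
    fit <- with_seed(substream_seed(seed, 200L + it), {
      randomForest::randomForest(
        x = X_all[, current, drop = FALSE], y = y, ntree = n_trees,
        importance = TRUE, strata = y, sampsize = c(n_min, n_min))
    })
    sizes <- c(sizes, length(current))
    errs <- c(errs, fit$err.rate[n_trees, "OOB"])
    subsets[[it]] <- current
    if (length(current) == 2) break
    imp <- randomForest::importance(fit, type = 1, scale = TRUE)[, 1]
    current <- current[current != names(which.min(imp[current]))]
  }
  # argmin OOB-ER; ties towards the smaller subset (later iteration)
  best <- max(which(errs <= min(errs) + 1e-12))
  list(best_loci = subsets[[best]], best_oob_er = errs[best],
       trajectory = data.frame(n_loci = sizes, oob_er = errs))
}

#' Partial redundancy-analysis outlier scan
#'
#' Partial RDA of genotypes on the ecotope indicator, conditioning on spatial
#' covariates: genotypes and the indicator are residualised on the
#' covariates, the residualised genotypes are regressed on the residualised
#' indicator, and the principal component of the fitted-value matrix gives
#' the single constrained axis (the predictor is binary). Per-locus loadings
#' on that axis are z-scored; loci beyond +/-2 SD (permissive) and +/-3 SD
#' (conservative) are flagged. Model significance is assessed by permuting
#' the residualised indicator and recomputing the pseudo-F.
#'
#' @param gm a `genotype_matrix`.
#' @param spatial_covs covariates from [spatial_covariates()], or `NULL`.
#' @param sd_thresholds numeric length-2 (default `c(2, 3)`).
#' @param n_perm permutations for the axis test (default 999).
#' @param seed integer seed.
#' @return list with `loadings`, `z`, `flag_2sd`, `flag_3sd`,
#'   `variance_explained`, `pseudo_f`, `p`, `scores` (per-sample axis scores).
#' @export
rda_scan <- function(gm, spatial_covs = NULL, sd_thresholds = c(2, 3),
                     n_perm = 999, seed = 1L) {
  y <- gm$meta$ecotope
  if (length(unique(y)) < 2) stop("both ecotopes must be present")
  G <- centred_genotypes(gm)
  h <- as.numeric(y == "domestic")
  if (!is.null(spatial_covs)) {
    G <- residualise(G, spatial_covs)
    h <- as.numeric(residualise(matrix(h), spatial_covs))
  } else {
    h <- h - mean(h)
  }
  if (stats::sd(h) < 1e-12) stop("ecotope is constant after residualisation")
  ss_h <- sum(h^2)
  bhat <- crossprod(G, h) / ss_h          # per-locus regression coefficient
  # fitted = h %*% t(bhat): rank one, PCA axis = bhat direction
  loadings <- as.numeric(bhat) * sqrt(ss_h)  # scale so ss(loadings) = ss(fitted)
  names(loadings) <- colnames(gm$geno)
  ss_fit <- sum(loadings^2)
  ss_tot <- sum(G^2)
  z <- (loadings - mean(loadings)) / stats::sd(loadings)
  q_cond <- if (is.null(spatial_covs)) 1 else ncol(spatial_covs) + 1
  df_res <- nrow(G) - q_cond - 1
  pseudo_f <- (ss_fit / 1) / ((ss_tot - ss_fit) / df_res)
  hits <- with_seed(seed, {
    sum(vapply(seq_len(n_perm), function(b) {
      hp <- h[sample.int(length(h))]
      ssf <- sum((crossprod(G, hp) / sum(hp^2))^2) * sum(hp^2)
      fp <- ssf / ((ss_tot - ssf) / df_res)
      fp >= pseudo_f - 1e-12
    }, logical(1)))
  })
  list(loadings = loadings, z = z,
       flag_2sd = abs(z) > sd_thresholds[1],
       flag_3sd = abs(z) > sd_thresholds[2],
       variance_explained = ss_fit / ss_tot,
       pseudo_f = pseudo_f, p = (hits + 1) / (n_perm + 1),
       scores = as.numeric(G %*% (loadings / sqrt(ss_fit))))
}

## per-locus Wright FST (no finite-sample correction) and heterozygosity
## between groups, size-weighted
locus_fst_het <- function(gm, grouping) {
  labels <- group_labels(gm, grouping)
  cc <- group_locus_counts(gm, labels)
  ok <- cc$n >= 1
  p <- ifelse(ok, cc$alt / (2 * pmax(cc$n, 1)), NA)
  w <- t(t(cc$n) / colSums(cc$n))
  pbar <- colSums(w * p, na.rm = TRUE)
  varp <- colSums(w * sweep(p, 2, pbar)^2, na.rm = TRUE)
  he <- 2 * pbar * (1 - pbar)
  fst <- ifelse(pbar > 0 & pbar < 1, varp / (pbar * (1 - pbar)), NA)
  data.frame(locus = colnames(gm$geno), fst = fst, he = he,
             row.names = NULL)
}

#' FST-heterozygosity outlier scan with a trimmed chi-square null
#'
#' Per-locus Wright FST (no finite-sample correction) between groups; loci in
#' the tails of the FST distribution are trimmed away and a scaled chi-square
#' (degrees of freedom `df`, mean `mu`) is fitted to the retained loci by
#' truncated maximum likelihood (Brent search on `df`, with the mean profiled
#' by an inner search). Every locus with expected heterozygosity at or above
#' `he_min` gets a right-tail p-value against the fitted null;
#' Benjamini-Hochberg q-values are computed and loci with `q < q_cut` are
#' flagged.
#'
#' @param gm a `genotype_matrix`.
#' @param grouping `"site"`, `"ecotope"` or `"site_ecotope"`.
#' @param trim_low,trim_high fractions of loci trimmed from the low/high FST
#'   tails before fitting (defaults 0.06 and 0.35).
#' @param he_min heterozygosity gate: loci below it are never tested or
#'   flagged (default 0.1).
#' @param q_cut flagging threshold on the q-value (default 0.05).
#' @return list with `table` (locus, fst, he, p, q, flag), `df`, `mean_fst`,
#'   `n_trimmed`.
#' @export
outflank_scan <- function(gm, grouping = "ecotope", trim_low = 0.06,
                          trim_high = 0.35, he_min = 0.1, q_cut = 0.05) {
  tab <- locus_fst_het(gm, grouping)
  if (sum(!is.na(tab$fst)) < 50) {
    warning("fewer than 50 usable loci; the null fit will be unstable")
  }
  usable <- !is.na(tab$fst) & tab$fst >= 0
  fst <- tab$fst[usable]
  qs <- stats::quantile(fst, c(trim_low, 1 - trim_high))
  core <- fst[fst >= qs[1] & fst <= qs[2]]
  core <- core[core > 0]
  if (length(core) < 10) stop("null fit failed: too few loci after trimming")
  # truncated scaled chi-square likelihood on [lo, hi]. The (df, mean) pair is
  # ridge-degenerate under free joint ML on a truncated window, so the mean is
  # profiled out by a moment constraint: for each df, mu is the value whose
  # *truncated* expectation equals the trimmed sample mean; df is then chosen
  # by Brent search on the truncated likelihood.
  lo <- qs[[1]]; hi <- qs[[2]]
  mbar <- mean(core)
  trunc_mean <- function(df, mu) {
    sc <- df / mu
    z <- stats::pchisq(hi * sc, df) - stats::pchisq(lo * sc, df)
    if (z <= 0) return(NA_real_)
    mu * (stats::pchisq(hi * sc, df + 2) - stats::pchisq(lo * sc, df + 2)) / z
  }
  mu_of_df <- function(df) {
    f <- function(mu) trunc_mean(df, mu) - mbar
    lo_mu <- mbar * 1e-3; hi_mu <- mbar * 50
    if (!is.finite(f(lo_mu)) || !is.finite(f(hi_mu)) ||
        f(lo_mu) * f(hi_mu) > 0) return(mbar)
    stats::uniroot(f, c(lo_mu, hi_mu), tol = mbar * 1e-8)$root
  }
  nll <- function(df) {
    mu <- mu_of_df(df)
    sc <- df / mu
    z <- stats::pchisq(hi * sc, df) - stats::pchisq(lo * sc, df)
    if (z <= 0) return(1e10)
    -sum(stats::dchisq(core * sc, df, log = TRUE) + log(sc)) +
      length(core) * log(z)
  }
  opt_df <- stats::optimize(nll, interval = c(1, 200))
  df_hat <- opt_df$minimum
  mu_hat <- mu_of_df(df_hat)
  if (!is.finite(opt_df$objective)) stop("null fit failed to converge")
  sc <- df_hat / mu_hat
  tab$p <- NA_real_
  test <- usable & tab$he >= he_min
  tab$p[test] <- stats::pchisq(tab$fst[test] * sc, df_hat, lower.tail = FALSE)
  tab$q <- NA_real_
  tab$q[test] <- stats::p.adjust(tab$p[test], method = "BH")
  tab$flag <- !is.na(tab$q) & tab$q < q_cut
  list(table = tab, df = df_hat, mean_fst = mu_hat,
       n_trimmed = sum(usable) - length(core))
}

#' FST-heterozygosity outlier scan with smoothed empirical quantiles
#'
#' Distribution-free variant: loci are binned by heterozygosity into
#' equal-count bins, per-bin `alpha/2` and `1 - alpha/2` FST quantiles are
#' taken, the quantile series is smoothed with a 3-bin moving average, and
#' the envelope is interpolated at each locus's heterozygosity. Loci outside
#' the envelope are flagged.
#'
#' @param gm a `genotype_matrix`.
#' @param grouping `"site"`, `"ecotope"` or `"site_ecotope"`.
#' @param alpha total flag level (default 0.05, split between the two tails).
#' @param n_bins number of heterozygosity bins (default 10; reduced with a
#'   warning when loci are few).
#' @return list with `table` (locus, fst, he, lower, upper, flag),
#'   `envelope` (bin mids and smoothed quantiles).
#' @export
fsthet_scan <- function(gm, grouping = "ecotope", alpha = 0.05, n_bins = 10) {
  tab <- locus_fst_het(gm, grouping)
  usable <- !is.na(tab$fst)
  n_use <- sum(usable)
  while (n_bins > 2 && n_use / n_bins < 20) {
    n_bins <- n_bins - 1
  }
  if (n_use / n_bins < 5) {
    warning("very few loci per heterozygosity bin; envelope will be coarse")
  }
  ord <- order(tab$he[usable])
  idx_use <- which(usable)[ord]
  bin <- ceiling(seq_along(idx_use) / (length(idx_use) / n_bins))
  bin <- pmin(bin, n_bins)
  mids <- tapply(tab$he[idx_use], bin, stats::median)
  loq <- tapply(tab$fst[idx_use], bin, stats::quantile, alpha / 2)
  hiq <- tapply(tab$fst[idx_use], bin, stats::quantile, 1 - alpha / 2)
  smooth3 <- function(x) {
    n <- length(x)
    vapply(seq_len(n), function(i)
      mean(x[max(1, i - 1):min(n, i + 1)]), numeric(1))
  }
  loq <- smooth3(loq); hiq <- smooth3(hiq)
  hiq <- pmax(hiq, loq)                    # envelope non-crossing
  interp <- function(q) stats::approx(mids, q, xout = tab$he, rule = 2)$y
  tab$lower <- interp(loq); tab$upper <- interp(hiq)
  tab$flag <- usable & (tab$fst > tab$upper | tab$fst < tab$lower)
  list(table = tab,
       envelope = data.frame(he = as.numeric(mids), lower = loq, upper = hiq))
}

#' Combine outlier-scan flags into a consensus report
#'
#' @param ... named logical vectors (or single-column flag data.frames) over
#'   the same loci, one per method.
#' @return list with `flags` (locus x method logical matrix),
#'   `method_count` per locus, and consensus sets `at_least_2`, `at_least_3`,
#'   `all_methods`.
#' @export
consensus <- function(...) {
  methods <- list(...)
  if (is.null(names(methods)) || any(names(methods) == "")) {
    stop("every method's flags must be named")
  }
  loci <- names(methods[[1]])
  for (m in methods) {
    if (is.null(names(m)) || !identical(sort(names(m)), sort(loci))) {
      stop("mismatched locus sets between methods")
    }
  }
  flags <- vapply(methods, function(m) as.logical(m[loci]),
                  logical(length(loci)))
  rownames(flags) <- loci
  cnt <- rowSums(flags)
  list(flags = flags, method_count = cnt,
       at_least_2 = loci[cnt >= 2],
       at_least_3 = loci[cnt >= 3],
       all_methods = loci[cnt == length(methods)])
}

#' Run the full outlier-scan suite on an ecotope contrast
#'
#' Convenience wrapper: spatial covariates, RF ranking + backwards purge,
#' partial RDA scan, and both FST-heterozygosity scans, with a consensus
#' report over the four flag sets.
#'
#' @param gm a `genotype_matrix` with both ecotopes.
#' @param n_trees,rf_threshold passed to [rf_rank()].
#' @param seed integer seed.
#' @return list with the individual results (`rf`, `purge`, `rda`,
#'   `outflank`, `fsthet`) and `consensus`.
#' @export
outlier_suite <- function(gm, n_trees = 5000, rf_threshold = 3, seed = 1L) {
  covs <- spatial_covariates(gm)
  rf <- rf_rank(gm, covs, n_trees = n_trees, threshold = rf_threshold,
                seed = substream_seed(seed, 21L))
  loci <- colnames(gm$geno)
  purge <- NULL
  rf_flag <- stats::setNames(rep(FALSE, length(loci)), loci)
  if (length(rf$ranked_loci) >= 3) {
    purge <- rf_backwards_purge(gm, rf$ranked_loci, covs,
                                n_trees = max(1000, n_trees %/% 2),
                                seed = substream_seed(seed, 22L))
    rf_flag[purge$best_loci] <- TRUE
  } else {
    rf_flag[rf$ranked_loci] <- TRUE
  }
  rda <- rda_scan(gm, covs, seed = substream_seed(seed, 23L))
  of <- outflank_scan(gm, "ecotope")
  fh <- fsthet_scan(gm, "ecotope")
  cons <- consensus(
    rf = rf_flag,
    rda = stats::setNames(rda$flag_2sd, loci),
    outflank = stats::setNames(of$table$flag, of$table$locus),
    fsthet = stats::setNames(fh$table$flag, fh$table$locus))
  list(rf = rf, purge = purge, rda = rda, outflank = of, fsthet = fh,
       consensus = cons)
}
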