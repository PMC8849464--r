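#' Simulation configuration for the synthetic landscape generator
#'
#' Defaults emulate the study design the package targets: ~25 collection
#' sites of ~10 bugs each, 7 sites with both domestic and wild groups,
#' ~2,500 biallelic SNPs on a 250 m grid, spatially autocorrelated site
#' allele frequencies whose correlation decays with effective (resistance)
#' distance, and a small set of loci carrying a domestic-associated
#' allele-frequency shift.
#'
#' @param n_sites number of collection sites.
#' @param samples_per_site diploid samples per site (dual-ecotope sites split
#'   them between the two ecotopes).
#' @param n_dual_sites sites carrying both domestic and wild groups.
#' @param n_loci number of biallelic loci.
#' @param n_outlier_loci loci given the domestic ecotope shift.
#' @param grid_shape raster rows/cols.
#' @param cell_size cell edge, metres.
#' @param gaussian_field_range spatial autocorrelation length of the
#'   elevation field, metres.
#' @param true_transform list with `variant`, `shape`, `max_resistance`: the
#'   monomolecular transform that defines the true resistance surface.
#' @param covariance_scale effective distance at which between-site
#'   allele-frequency correlation decays by 1/e; `NULL` = median pairwise
#'   effective distance (a scale-free default).
#' @param baseline_fst dimensionless F of the Beta (F-model) marginals,
#'   in (0, 1): the expected neutral differentiation level.
#' @param ecotope_shift logit-scale allele-frequency shift added to domestic
#'   groups at outlier loci.
#' @param missing_rate missing-call fraction, completely at random.
#' @param min_separation minimum site separation, metres.
#' @param seed integer seed; all stages draw substreams from it.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_sites = 25, samples_per_site = 10, n_dual_sites = 7,
                       n_loci = 2500, n_outlier_loci = 5,
                       grid_shape = c(100, 100), cell_size = 250,
                       gaussian_field_range = 5000,
                       true_transform = list(variant = 1, shape = 0.3,
                                             max_resistance = 100),
                       covariance_scale = NULL, baseline_fst = 0.1,
                       ecotope_shift = 2, missing_rate = 0.02,
                       min_separation = 1000, seed = 1L) {
  cfg <- list(n_sites = n_sites, samples_per_site = samples_per_site,
              n_dual_sites = n_dual_sites, n_loci = n_loci,
              n_outlier_loci = n_outlier_loci, grid_shape = grid_shape,
              cell_size = cell_size,
              gaussian_field_range = gaussian_field_range,
              true_transform = true_transform,
              covariance_scale = covariance_scale,
              baseline_fst = baseline_fst, ecotope_shift = ecotope_shift,
              missing_rate = missing_rate, min_separation = min_separation,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (cfg$n_outlier_loci >= cfg$n_loci) stop("n_outlier_loci must be < n_loci")
  if (cfg$baseline_fst <= 0 || cfg$baseline_fst >= 1) {
    stop("baseline_fst must lie in (0, 1)")
  }
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1) {
    stop("missing_rate must lie in [0, 1)")
  }
  if (prod(cfg$grid_shape) < cfg$n_sites) {
    stop("grid too small to place all sites on distinct cells")
  }
  if (cfg$n_dual_sites > cfg$n_sites) stop("n_dual_sites must be <= n_sites")
  invisible(cfg)
}

#' Simulate a spatially autocorrelated elevation field
#'
#' Gaussian random field with exponential covariance
#' `C(h) = exp(-h / range)`, simulated by circulant embedding on a doubled
#' torus (FFT); small negative embedding eigenvalues are clipped to zero.
#' The unit-variance field is mapped to elevation as `1500 + 500 z`, clipped
#' to `[0, 3000]` m a.s.l., so longer ranges give smoother (and in the limit
#' spatially constant) surfaces.
#'
#' @param grid_shape integer rows/cols.
#' @param cell_size cell edge, metres.
#' @param range correlation length, metres.
#' @param seed integer seed.
#' @return a continuous `raster_surface`.
#' @export
generate_elevation_field <- function(grid_shape, cell_size, range, seed = 1L) {
  if (any(grid_shape < 1)) stop("non-positive grid dimensions")
  if (range <= 0) stop("range must be positive")
  nr <- grid_shape[1]; nc <- grid_shape[2]
  M <- 2 * nr; N <- 2 * nc
  # torus distances on the doubled grid
  di <- pmin(0:(M - 1), M - 0:(M - 1)) * cell_size
  dj <- pmin(0:(N - 1), N - 0:(N - 1)) * cell_size
  h <- sqrt(outer(di^2, dj^2, `+`))
  lam <- Re(stats::fft(exp(-h / range)))
  lam <- pmax(lam, 0)
  z <- with_seed(seed, {
    # unit-variance real and imaginary parts: Re() of the synthesis then has
    # the target covariance (the imaginary part is an independent copy)
    xi <- matrix(complex(real = stats::rnorm(M * N),
                         imaginary = stats::rnorm(M * N)), M, N)
    Re(stats::fft(sqrt(lam) * xi) / sqrt(M * N))[seq_len(nr), seq_len(nc)]
  })
  elev <- pmin(pmax(1500 + 500 * z, 0), 3000)
  raster_surface(elev, cell_size, kind = "continuous")
}

#' Place collection sites on a raster
#'
#' Uniformly samples distinct valid cells, rejecting layouts that violate the
#' minimum pairwise separation, with bounded retries. The first
#' `n_dual` sites carry both domestic and wild groups; the remainder
#' alternate between single-ecotope domestic and wild sites.
#'
#' @param raster a `raster_surface`.
#' @param n_sites number of sites (>= 2).
#' @param min_separation minimum pairwise distance, metres.
#' @param n_dual number of dual-ecotope sites.
#' @param seed integer seed.
#' @param max_tries placement attempts before giving up.
#' @return data.frame (`site_table`): `site_id`, `row`, `col`, `x`, `y`,
#'   `has_domestic`, `has_wild`.
#' @export
place_sites <- function(raster, n_sites, min_separation = 0, n_dual = 0,
                        seed = 1L, max_tries = 200L) {
  if (n_sites < 2) stop("need at least 2 sites")
  cc <- cell_centres(raster)
  cc <- cc[!is.na(raster$values[cbind(cc$row, cc$col)]), ]
  if (nrow(cc) < n_sites) stop("not enough valid cells for the sites")
  diag_len <- sqrt(sum((dim(raster$values) * raster$cell_size)^2))
  if (min_separation > diag_len) {
    stop("placement error: min_separation exceeds the raster diagonal")
  }
  # sequential dart throwing: add sites one at a time, restart when stuck
  sel <- with_seed(seed, {
    found <- NULL
    for (try in seq_len(max_tries)) {
      idx <- sample.int(nrow(cc), 1)
      stuck <- FALSE
      while (length(idx) < n_sites && !stuck) {
        cand <- sample.int(nrow(cc), min(200L, nrow(cc)))
        d2min <- vapply(cand, function(k)
          min((cc$x[idx] - cc$x[k])^2 + (cc$y[idx] - cc$y[k])^2), numeric(1))
        ok <- cand[d2min >= min_separation^2 & !(cand %in% idx)]
        if (length(ok)) idx <- c(idx, ok[1]) else stuck <- TRUE
      }
      if (length(idx) == n_sites) {
        found <- idx
        break
      }
    }
    found
  })
  if (is.null(sel)) {
    stop("placement error: could not satisfy min_separation after ",
         max_tries, " tries")
  }
  out <- cc[sel, ]
  out$site_id <- sprintf("S%02d", seq_len(n_sites))
  dual <- seq_len(n_sites) <= n_dual
  single_dom <- !dual & ((seq_len(n_sites) - n_dual) %% 2 == 1)
  out$has_domestic <- dual | single_dom
  out$has_wild <- dual | (!dual & !single_dom)
  rownames(out) <- NULL
  out[, c("site_id", "row", "col", "x", "y", "has_domestic", "has_wild")]
}

#' Simulate genotypes with known isolation-by-resistance structure
#'
#' Gaussian-copula F-model: per locus, an ancestral frequency
#' `p0 ~ Beta(2, 2)` is drawn; a latent site vector `z` follows a
#' multivariate normal with correlation `exp(-d_eff / lambda)`; each `z` is
#' mapped through the standard-normal CDF to a quantile of
#' `Beta(p0 (1-F)/F, (1-p0)(1-F)/F)`, giving site frequencies with F-model
#' marginals (expected neutral FST of about `F`) and spatial correlation that
#' decays with effective distance. Outlier loci add the configured logit-scale
#' shift to every domestic group. Genotypes are binomial(2, p) per diploid;
#' missingness is completely at random.
#'
#' @param effective_dm a `dist_matrix` of site effective distances.
#' @param sites site table from [place_sites()] (labels must match).
#' @param config a `sim_config`.
#' @return list with `gm` (a `genotype_matrix`) and `truth` (list:
#'   `outlier_locus_ids`, `p0`, `site_frequencies` (group x locus),
#'   `lambda`, `effective_dm`).
#' @export
simulate_genotypes <- function(effective_dm, sites, config) {
  validate_sim_config(config)
  n_sites <- nrow(sites)
  stopifnot(all(rownames(effective_dm) == sites$site_id))
  D <- unclass(effective_dm)
  lambda <- config$covariance_scale
  if (is.null(lambda)) lambda <- stats::median(D[lower.tri(D)])
  Corr <- exp(-D / lambda)
  diag(Corr) <- diag(Corr) + 1e-8
  Lc <- tryCatch(t(chol(Corr)), error = function(e)
    stop("simulation error: site correlation not positive definite"))
  Fv <- config$baseline_fst
  nl <- config$n_loci

  res <- with_seed(substream_seed(config$seed, 13L), {
    p0 <- stats::rbeta(nl, 2, 2)
    Z <- Lc %*% matrix(stats::rnorm(n_sites * nl), n_sites, nl)
    U <- stats::pnorm(Z)
    a <- rep(p0 * (1 - Fv) / Fv, each = n_sites)
    b <- rep((1 - p0) * (1 - Fv) / Fv, each = n_sites)
    P <- matrix(stats::qbeta(as.vector(U), a, b), n_sites, nl)
    outliers <- sort(sample.int(nl, config$n_outlier_loci))

    # group structure: site x ecotope
    grp <- list()
    for (k in seq_len(n_sites)) {
      n_tot <- config$samples_per_site
      if (sites$has_domestic[k] && sites$has_wild[k]) {
        nd <- ceiling(n_tot / 2)
        grp[[length(grp) + 1]] <- list(site = k, eco = "domestic", n = nd)
        grp[[length(grp) + 1]] <- list(site = k, eco = "wild", n = n_tot - nd)
      } else {
        eco <- if (sites$has_domestic[k]) "domestic" else "wild"
        grp[[length(grp) + 1]] <- list(site = k, eco = eco, n = n_tot)
      }
    }
    n_samp <- sum(vapply(grp, `[[`, numeric(1), "n"))
    geno <- matrix(NA_integer_, n_samp, nl)
    meta <- data.frame(sample_id = character(n_samp), site_id = character(n_samp),
                       ecotope = character(n_samp), year = integer(n_samp),
                       x = numeric(n_samp), y = numeric(n_samp))
    gfreq <- matrix(0, length(grp), nl)
    gnames <- character(length(grp))
    row0 <- 0L
    clamp <- function(p) pmin(pmax(p, 1e-9), 1 - 1e-9)
    for (gi in seq_along(grp)) {
      g <- grp[[gi]]
      p <- P[g$site, ]
      if (g$eco == "domestic") {
        p[outliers] <- stats::plogis(
          stats::qlogis(clamp(p[outliers])) + config$ecotope_shift)
      }
      gfreq[gi, ] <- p
      gnames[gi] <- paste(sites$site_id[g$site], g$eco, sep = ":")
      if (g$n > 0) {
        rows <- row0 + seq_len(g$n)
        geno[rows, ] <- matrix(stats::rbinom(g$n * nl, 2, rep(p, each = g$n)),
                               g$n, nl)
        meta$site_id[rows] <- sites$site_id[g$site]
        meta$ecotope[rows] <- g$eco
        meta$year[rows] <- 2015L
        meta$x[rows] <- sites$x[g$site]
        meta$y[rows] <- sites$y[g$site]
        row0 <- row0 + g$n
      }
    }
    meta$sample_id <- sprintf("I%04d", seq_len(n_samp))
    if (config$missing_rate > 0) {
      drop <- stats::runif(length(geno)) < config$missing_rate
      geno[drop] <- NA_integer_
    }
    rownames(gfreq) <- gnames
    list(geno = geno, meta = meta, p0 = p0, gfreq = gfreq, outliers = outliers)
  })

  locus_ids <- sprintf("L%05d", seq_len(nl))
  colnames(res$gfreq) <- locus_ids
  gm <- genotype_matrix(res$geno, res$meta, locus_ids)
  truth <- list(outlier_locus_ids = locus_ids[res$outliers],
                p0 = stats::setNames(res$p0, locus_ids),
                site_frequencies = res$gfreq, lambda = lambda,
                effective_dm = effective_dm)
  list(gm = gm, truth = truth)
}

#' Simulate a complete synthetic landscape-genomics dataset
#'
#' Chains the generator stages: elevation field, true resistance surface
#' (monomolecular transform of the rescaled elevation), commute-time
#' effective distances between placed sites, and spatially structured
#' genotypes with injected outlier loci.
#'
#' @param config a `sim_config`.
#' @return list with `gm`, `truth` (including `true_resistance` and
#'   `true_effective_dm`), `sites`, `elevation`, `config`.
#' @export
simulate_landscape_dataset <- function(config = sim_config()) {
  elev <- generate_elevation_field(config$grid_shape, config$cell_size,
                                   config$gaussian_field_range,
                                   seed = substream_seed(config$seed, 11L))
  sites <- place_sites(elev, config$n_sites, config$min_separation,
                       n_dual = config$n_dual_sites,
                       seed = substream_seed(config$seed, 12L))
  tt <- config$true_transform
  resistance <- monomolecular(rescale_surface(elev), tt$variant, tt$shape,
                              tt$max_resistance)
  graph <- build_conductance_graph(resistance)
  eff <- commute_distance(graph, site_nodes(graph, sites))
  sim <- simulate_genotypes(eff, sites, config)
  sim$truth$true_resistance <- resistance
  sim$truth$true_effective_dm <- eff
  list(gm = sim$gm, truth = sim$truth, sites = sites, elevation = elev,
       config = config)
}
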