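#' Euclidean geographic distances between sites, in km
#'
#' @param sites data.frame with `site_id`, `x`, `y` (projected metres).
#' @return a `dist_matrix` of kind `"geographic_km"`.
#' @export
geographic_distances <- function(sites) {
  if (anyNA(sites$x) || anyNA(sites$y)) stop("missing site coordinates")
  d <- as.matrix(stats::dist(cbind(sites$x, sites$y))) / 1000
  dist_matrix(d, as.character(sites$site_id), kind = "geographic_km")
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation of lower triangles; significance by jointly permuting
#' rows and columns of the second matrix. One-sided (positive association)
#' p-value with the `(b + 1) / (B + 1)` estimator.
#'
#' @param dm_a,dm_b `dist_matrix` objects over the same labels.
#' @param n_perm number of permutations (default 9999).
#' @param seed integer seed.
#' @return list with `r_m`, `p`, `n_perm`, `n_groups`.
#' @export
mantel_test <- function(dm_a, dm_b, n_perm = 9999, seed = 1L) {
  if (nrow(dm_a) < 4) stop("mantel test needs at least 4 groups")
  dm_b <- align_dm(dm_b, rownames(dm_a))
  a <- lower_tri(unclass(dm_a)); b <- lower_tri(unclass(dm_b))
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    return(list(r_m = NA_real_, p = NA_real_, n_perm = n_perm,
                n_groups = nrow(dm_a), note = "constant matrix"))
  }
  r <- stats::cor(a, b)
  bm <- unclass(dm_b)
  n <- nrow(bm)
  hits <- with_seed(seed, {
    sum(vapply(seq_len(n_perm), function(i) {
      idx <- sample.int(n)
      stats::cor(a, lower_tri(bm[idx, idx])) >= r - 1e-12
    }, logical(1)))
  })
  list(r_m = r, p = (hits + 1) / (n_perm + 1), n_perm = n_perm, n_groups = n)
}

#' Build a pair table for MLPE regression
#'
#' Expands matched genetic and predictor distance matrices into one row per
#' unordered pair of populations. The predictor is centred about its mean so
#' the intercept and slope estimates are uncorrelated. With a stratum
#' assignment (e.g. domestic/wild per site), pairs can be restricted to those
#' within a stratum and carry the stratum as a factor for interaction models.
#'
#' @param genetic_dm `dist_matrix` of genetic distances (response).
#' @param predictor_dm `dist_matrix` of geographic or effective distances.
#' @param strata optional named character vector: stratum of each population
#'   label. Cross-stratum pairs are dropped.
#' @param center logical; centre the predictor about its mean (default TRUE).
#' @return data.frame with columns `pop1`, `pop2`, `gdist`, `xdist` (centred),
#'   `xdist_raw` and, if given, `ecotope` (factor); attribute `"x_mean"`.
#' @export
pair_table <- function(genetic_dm, predictor_dm, strata = NULL, center = TRUE) {
  labs <- rownames(genetic_dm)
  predictor_dm <- align_dm(predictor_dm, labs)
  idx <- which(lower.tri(unclass(genetic_dm)), arr.ind = TRUE)
  out <- data.frame(pop1 = labs[idx[, 2]], pop2 = labs[idx[, 1]],
                    gdist = unclass(genetic_dm)[idx],
                    xdist_raw = unclass(predictor_dm)[idx])
  if (!is.null(strata)) {
    if (!all(labs %in% names(strata))) {
      stop("strata must name every population label")
    }
    s1 <- strata[out$pop1]; s2 <- strata[out$pop2]
    out <- out[s1 == s2, , drop = FALSE]
    out$ecotope <- factor(strata[out$pop1])
  }
  x_mean <- if (center) mean(out$xdist_raw) else 0
  out$xdist <- out$xdist_raw - x_mean
  attr(out, "x_mean") <- x_mean
  rownames(out) <- NULL
  out
}

#' Ecotope-stratified isolation-by-distance analysis
#'
#' The domestic and wild strata are analysed the way field studies usually
#' do: genetic and geographic distance matrices are built separately over the
#' sites where each ecotope was collected (a site with both ecotopes
#' contributes its domestic samples to the domestic matrix and its wild
#' samples to the wild one), Mantel tests are run per stratum, and a joint
#' MLPE model with an ecotope main effect and an ecotope-by-distance
#' interaction contrasts the two distance-decay slopes.
#'
#' @param gm a `genotype_matrix`.
#' @param genetic_stat `"gst_hedrick"`, `"fst_nei"` or `"fst_meirmans"`.
#' @param min_sites minimum sites per stratum to analyse it (default 4).
#' @param n_perm Mantel permutations.
#' @param seed integer seed.
#' @return list with `mantel` (per ecotope), `fit_main`, `fit_interaction`,
#'   `contrast`, and the per-ecotope distance matrices.
#' @export
ibd_ecotope_analysis <- function(gm, genetic_stat = "gst_hedrick",
                                 min_sites = 4, n_perm = 9999, seed = 1L) {
  stat_fun <- switch(genetic_stat, gst_hedrick = gst_hedrick,
                     fst_nei = function(g, gr) pairwise_fst_nei(g, gr, n_perm = 0),
                     fst_meirmans = fst_meirmans,
                     stop("unknown genetic_stat"))
  mantel <- list(); pairs_all <- NULL; dms <- list()
  for (eco in c("domestic", "wild")) {
    keep <- gm$meta$ecotope == eco
    sub <- subset_genotypes(gm, keep)
    sizes <- table(sub$meta$site_id)
    sub <- subset_genotypes(sub, sub$meta$site_id %in%
                              names(sizes)[sizes >= 2])
    n_sites <- length(unique(sub$meta$site_id))
    if (n_sites < min_sites) next
    gdm <- stat_fun(sub, "site")
    sites <- unique(sub$meta[, c("site_id", "x", "y")])
    geo <- geographic_distances(sites)
    geo <- align_dm(geo, rownames(gdm))
    mantel[[eco]] <- mantel_test(gdm, geo, n_perm = n_perm, seed = seed)
    pt <- pair_table(gdm, geo, center = FALSE)
    pt$pop1 <- paste(pt$pop1, eco, sep = ":")
    pt$pop2 <- paste(pt$pop2, eco, sep = ":")
    pt$ecotope <- eco
    pairs_all <- rbind(pairs_all, pt)
    dms[[eco]] <- list(genetic = gdm, geographic = geo)
  }
  if (is.null(pairs_all) || length(unique(pairs_all$ecotope)) < 2) {
    stop("need at least ", min_sites, " sites in each ecotope stratum")
  }
  pairs_all$ecotope <- factor(pairs_all$ecotope,
                              levels = c("domestic", "wild"))
  pairs_all$xdist <- pairs_all$xdist_raw - mean(pairs_all$xdist_raw)
  fit_main <- mlpe(gdist ~ xdist + ecotope, pairs_all)
  fit_int <- mlpe(gdist ~ xdist * ecotope, pairs_all)
  list(mantel = mantel, fit_main = fit_main, fit_interaction = fit_int,
       contrast = slope_contrast(fit_int), pairs = pairs_all,
       matrices = dms)
}

#' Isolation-by-distance analysis for one or two ecotope strata
#'
#' Convenience wrapper reproducing the standard workflow: Mantel tests per
#' stratum, a joint MLPE fit with stratum main effect, the interaction model,
#' and the slope contrast between strata.
#'
#' @param genetic_dm,predictor_dm matched `dist_matrix` objects.
#' @param strata named character vector (population label to stratum).
#' @param n_perm Mantel permutations.
#' @param seed integer seed.
#' @return list with `mantel` (per stratum), `fit_main`, `fit_interaction`,
#'   `contrast`.
#' @export
ibd_analysis <- function(genetic_dm, predictor_dm, strata, n_perm = 9999,
                         seed = 1L) {
  mantel <- lapply(split(names(strata), strata), function(labs) {
    if (length(labs) < 4) return(NULL)
    mantel_test(align_dm(genetic_dm, labs), align_dm(predictor_dm, labs),
                n_perm = n_perm, seed = seed)
  })
  pairs <- pair_table(genetic_dm, predictor_dm, strata = strata)
  fit_main <- mlpe(gdist ~ xdist + ecotope, pairs)
  fit_int <- mlpe(gdist ~ xdist * ecotope, pairs)
  list(mantel = mantel, fit_main = fit_main, fit_interaction = fit_int,
       contrast = slope_contrast(fit_int))
}
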