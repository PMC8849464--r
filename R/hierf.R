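## Variance components of the unbalanced fully-nested random model on allele
## indicators, vectorised over loci.
##
## Levels run from the outermost declared factor down to individuals and
## gametes: grand > factors[[1]] > factors[[2]] > ... > individual > gamete.
## Factors must be nested (each inner group belongs to one outer group); the
## function enforces this by building interaction labels.
##
## For each level the expected sum of squares is a linear combination of the
## variance components with coefficients computed exactly from the group
## sizes; the (upper-triangular) system is solved per locus by
## back-substitution. Returns a loci x components matrix (one column per
## declared factor, plus "ind" and "gamete"); loci without data are NA.
nested_components <- function(geno, factors) {
  n_samp <- nrow(geno); n_loci <- ncol(geno)
  called <- !is.na(geno)
  g0 <- geno; g0[!called] <- 0L
  nf <- length(factors)
  L <- nf + 2L                      # declared levels + individual + gamete
  lab <- vector("list", nf)
  lv <- rep("0", n_samp)
  for (k in seq_len(nf)) {
    lv <- paste(lv, as.character(factors[[k]]), sep = "/")
    lab[[k]] <- lv                  # interaction labels enforce nesting
  }
  Cs <- lapply(lab, function(l) rowsum(called + 0, l))   # called diploids
  Ss <- lapply(lab, function(l) rowsum(g0, l))           # allele sums
  C_tot <- colSums(called)
  S_tot <- colSums(g0)

  safe_div <- function(num, den) ifelse(den > 0, num / pmax(den, 1), 0)

  # T_l = sum over groups at level l of (allele sum)^2 / gene copies
  Tl <- c(list(safe_div(S_tot^2, 2 * C_tot)),
          lapply(seq_len(nf), function(k)
            colSums(safe_div(Ss[[k]]^2, 2 * Cs[[k]]))),
          list(colSums(safe_div(g0^2, 2 * called)),   # individuals
               S_tot))                                 # gametes (0/1 values)

  groups_at <- function(k) colSums(Cs[[k]] > 0)
  # K(l, m): sum over groups g at level l of
  #          sum over units u at level m within g of n_u^2 / n_g,
  # with n in gene copies; these are the exact E[sum n_g ybar_g^2] weights.
  K <- function(l, m) {
    if (m == nf + 2L) {                       # units = gametes
      if (l == 0) return(rep(1, n_loci))
      if (l <= nf) return(groups_at(l))
      if (l == nf + 1L) return(C_tot)
      return(2 * C_tot)
    }
    if (m == nf + 1L) {                       # units = individuals (n_u = 2)
      if (l == 0) return(rep(2, n_loci))
      if (l <= nf) return(2 * groups_at(l))
      return(2 * C_tot)
    }
    Cm2 <- Cs[[m]]^2                          # units = factor-m groups
    if (l == 0) return(2 * safe_div(colSums(Cm2), C_tot))
    anc <- vapply(strsplit(rownames(Cs[[m]]), "/", fixed = TRUE),
                  function(p) paste(p[1:(l + 1)], collapse = "/"),
                  character(1))
    agg <- rowsum(Cm2, anc)
    Cl <- Cs[[l]][rownames(agg), , drop = FALSE]
    2 * colSums(safe_div(agg, Cl))
  }

  # E[SS_l] = sum_m [K(l, m) - K(l-1, m)] sigma^2_m: upper-triangular system,
  # solved per locus by back-substitution
  SS <- lapply(seq_len(L), function(l) Tl[[l + 1]] - Tl[[l]])
  A <- matrix(list(), L, L)
  for (l in seq_len(L)) for (m in l:L) A[[l, m]] <- K(l, m) - K(l - 1, m)
  comp <- matrix(NA_real_, n_loci, L)
  comp[, L] <- safe_div(SS[[L]], A[[L, L]])
  for (l in rev(seq_len(L - 1))) {
    acc <- SS[[l]]
    for (m in (l + 1):L) acc <- acc - A[[l, m]] * comp[, m]
    comp[, l] <- safe_div(acc, A[[l, l]])
  }
  comp[C_tot < 2, ] <- NA
  colnames(comp) <- c(names(factors), "ind", "gamete")
  comp
}

#' Hierarchical F-statistics with permutation tests
#'
#' Nested moment-based variance components on allele indicators (gamete-level
#' nested ANOVA), with components summed across loci. For a hierarchy
#' site > stratum-within-site (stratum = ecotope or collection year) the
#' reported statistics are `F_site/total` (among sites relative to total) and
#' `F_stratum/site` (among strata within sites). Confidence intervals by
#' bootstrapping loci; significance by permuting units at the level
#' immediately below the tested one (whole individuals among sites for the
#' site level; individuals among strata within their site for the stratum
#' level).
#'
#' @param gm a `genotype_matrix`.
#' @param within `"ecotope"`, `"year"`, or `NULL` for sites only.
#' @param n_perm permutations for p-values (default 999; 0 skips).
#' @param n_boot bootstrap replicates over loci for the 95% CI (default 200).
#' @param seed integer seed.
#' @return data.frame with one row per level: `level`, `f`, `ci_lo`, `ci_hi`,
#'   `p`; attribute `"components"` holds the summed variance components.
#' @export
hierarchical_f <- function(gm, within = c("ecotope", "year"), n_perm = 999,
                           n_boot = 200, seed = 1L) {
  site <- as.character(gm$meta$site_id)
  factors <- list(site = site)
  if (!is.null(within)) {
    within <- match.arg(within)
    sub <- as.character(gm$meta[[if (within == "ecotope") "ecotope" else "year"]])
    factors$stratum <- sub
  }
  comp <- nested_components(gm$geno, factors)
  s <- colSums(comp, na.rm = TRUE)
  f_of <- function(s) {
    tot <- sum(s)
    out <- c(site_total = s[[1]] / tot)
    if (length(s) == 4) {
      out <- c(out, stratum_site = s[[2]] / sum(s[-1]))
    }
    out
  }
  obs <- f_of(s)
  lv_names <- if (is.null(within)) "site/total" else
    c("site/total", paste0(within, "/site"))

  # bootstrap loci for CIs
  ci <- with_seed(substream_seed(seed, 1L), {
    reps <- replicate(n_boot, {
      idx <- sample.int(nrow(comp), replace = TRUE)
      f_of(colSums(comp[idx, , drop = FALSE], na.rm = TRUE))
    })
    reps <- matrix(reps, nrow = length(obs))
    t(apply(reps, 1, stats::quantile, c(0.025, 0.975), na.rm = TRUE))
  })

  p <- rep(NA_real_, length(obs))
  if (n_perm > 0) {
    # level 1: permute individuals among sites
    hits1 <- with_seed(substream_seed(seed, 2L), {
      sum(vapply(seq_len(n_perm), function(b) {
        idx <- sample.int(length(site))
        fac <- factors
        fac$site <- site[idx]
        if (!is.null(within)) fac$stratum <- factors$stratum[idx]
        fp <- f_of(colSums(nested_components(gm$geno, fac), na.rm = TRUE))
        fp[[1]] >= obs[[1]] - 1e-12
      }, logical(1)))
    })
    p[1] <- (hits1 + 1) / (n_perm + 1)
    if (length(obs) == 2) {
      # level 2: permute stratum labels within each site
      hits2 <- with_seed(substream_seed(seed, 3L), {
        sum(vapply(seq_len(n_perm), function(b) {
          strat <- factors$stratum
          for (sid in unique(site)) {
            w <- which(site == sid)
            strat[w] <- strat[w][sample.int(length(w))]
          }
          fp <- f_of(colSums(nested_components(
            gm$geno, list(site = site, stratum = strat)), na.rm = TRUE))
          fp[[2]] >= obs[[2]] - 1e-12
        }, logical(1)))
      })
      p[2] <- (hits2 + 1) / (n_perm + 1)
    }
  }
  singletons <- vapply(factors, function(f) length(unique(f)) < 2, logical(1))
  out <- data.frame(level = lv_names, f = as.numeric(obs),
                    ci_lo = ci[, 1], ci_hi = ci[, 2], p = p)
  if (any(singletons)) out$f[which(singletons)] <- NA
  attr(out, "components") <- s
  out
}
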