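## Nei/Chesser-corrected heterozygosity components for a set of groups,
## vectorised over loci. Returns per-locus HO, HS, HT, HT_max and the number
## of groups with data; loci need >= 2 called genotypes in every group.
het_components <- function(n, alt, het) {
  k <- nrow(n)
  ok <- colSums(n >= 2) == k
  n <- n[, ok, drop = FALSE]; alt <- alt[, ok, drop = FALSE]
  het <- het[, ok, drop = FALSE]
  p <- alt / (2 * n)
  ho <- colMeans(het / n)
  hs_raw <- colMeans(2 * p * (1 - p))
  n_harm <- k / colSums(1 / n)
  hs <- (n_harm / (n_harm - 1)) * (hs_raw - ho / (2 * n_harm))
  pbar <- colMeans(p)
  ht_raw <- 2 * pbar * (1 - pbar)
  ht <- ht_raw + hs / (2 * n_harm * k)
  # maximal-differentiation HT: each group's alleles recoded private
  ht_max_raw <- 1 - (colSums(p^2) + colSums((1 - p)^2)) / k^2
  ht_max <- ht_max_raw + hs / (2 * n_harm * k)
  list(ho = ho, hs = hs, ht = ht, ht_max = ht_max, k = k, loci_used = which(ok))
}

## multilocus differentiation statistics from averaged heterozygosities.
## Estimates are truncated at 0: the unbiased heterozygosity corrections can
## push undifferentiated pairs slightly negative, and downstream use as
## distance matrices requires non-negativity.
diff_from_components <- function(comp, statistic) {
  hs <- mean(comp$hs); ht <- mean(comp$ht); k <- comp$k
  if (ht <= 0) return(structure(0, flagged = TRUE))
  gst <- (ht - hs) / ht
  val <- switch(statistic,
                fst_nei = gst,
                gst_hedrick = {
                  if (hs >= 1) return(structure(0, flagged = TRUE))
                  k * (ht - hs) / ((k * ht - hs) * (1 - hs))
                },
                fst_meirmans = {
                  ht_max <- mean(comp$ht_max)
                  fst_max <- (ht_max - hs) / ht_max
                  if (fst_max <= 0) return(structure(0, flagged = TRUE))
                  gst / fst_max
                })
  max(val, 0)
}

pairwise_diff_matrix <- function(gm, grouping, statistic, n_perm = 0,
                                 seed = 1L) {
  labels <- group_labels(gm, grouping)
  groups <- sort(unique(labels))
  if (length(groups) < 2) stop("need at least 2 groups")
  sizes <- table(labels)
  if (any(sizes < 2)) {
    stop("group(s) with fewer than 2 samples: ",
         paste(names(sizes)[sizes < 2], collapse = ", "))
  }
  ng <- length(groups)
  vals <- matrix(0, ng, ng, dimnames = list(groups, groups))
  pmat <- matrix(NA_real_, ng, ng, dimnames = list(groups, groups))
  one_stat <- function(geno_a, geno_b) {
    lab <- rep(c("a", "b"), c(nrow(geno_a), nrow(geno_b)))
    g <- rbind(geno_a, geno_b)
    called <- !is.na(g); g0 <- g; g0[!called] <- 0L
    comp <- het_components(rowsum(called + 0, lab), rowsum(g0, lab),
                           rowsum((g == 1L & called) + 0, lab))
    diff_from_components(comp, statistic)
  }
  for (i in seq_len(ng - 1)) {
    for (j in seq(i + 1, ng)) {
      ga <- gm$geno[labels == groups[i], , drop = FALSE]
      gb <- gm$geno[labels == groups[j], , drop = FALSE]
      obs <- one_stat(ga, gb)
      vals[i, j] <- vals[j, i] <- as.numeric(obs)
      if (n_perm > 0) {
        pool <- rbind(ga, gb)
        na <- nrow(ga)
        hits <- with_seed(substream_seed(seed, i * 1000L + j), {
          sum(vapply(seq_len(n_perm), function(b) {
            idx <- sample.int(nrow(pool), na)
            as.numeric(one_stat(pool[idx, , drop = FALSE],
                                pool[-idx, , drop = FALSE])) >=
              as.numeric(obs) - 1e-12
          }, logical(1)))
        })
        pmat[i, j] <- pmat[j, i] <- (hits + 1) / (n_perm + 1)
      }
    }
  }
  dm <- dist_matrix(vals, groups, kind = statistic)
  if (n_perm > 0) {
    diag(pmat) <- 1
    list(dm = dm, p = pmat, q = adjust_p_matrix(pmat))
  } else {
    dm
  }
}

#' Pairwise Nei FST with permutation tests
#'
#' Nei (1973) `FST = (H_T - H_S) / H_T` per pair of groups, from multilocus
#' averaged heterozygosities with Nei & Chesser small-sample corrections
#' (unbiased within-group gene diversity). Significance by permuting
#' individuals between the two groups; Benjamini-Hochberg adjustment across
#' all pairs.
#'
#' @param gm a `genotype_matrix`.
#' @param grouping `"site"`, `"ecotope"` or `"site_ecotope"`.
#' @param n_perm permutations per pair (default 999; 0 skips testing).
#' @param seed integer seed.
#' @return with `n_perm > 0`, a list with `dm` (a `dist_matrix`), `p` and `q`
#'   (BH-adjusted) matrices; otherwise just the `dist_matrix`.
#' @export
pairwise_fst_nei <- function(gm, grouping = "site", n_perm = 999, seed = 1L) {
  pairwise_diff_matrix(gm, grouping, "fst_nei", n_perm, seed)
}

#' Pairwise Hedrick G''ST
#'
#' The double-corrected standardised differentiation of Meirmans & Hedrick
#' (2011): `G''_ST = k (H_T - H_S) / ((k H_T - H_S)(1 - H_S))`, which corrects
#' both for within-group diversity and for sampling a limited number of
#' groups (`k = 2` for a pair).
#'
#' @inheritParams pairwise_fst_nei
#' @return a `dist_matrix` (or list with p-values when `n_perm > 0`).
#' @export
gst_hedrick <- function(gm, grouping = "site", n_perm = 0, seed = 1L) {
  pairwise_diff_matrix(gm, grouping, "gst_hedrick", n_perm, seed)
}

#' Pairwise Meirmans standardised FST
#'
#' `F'_ST = F_ST / F_ST(max)`, where the maximum is obtained by recoding each
#' group's alleles as private (maximal differentiation given the observed
#' within-group diversity and sample sizes).
#'
#' @inheritParams pairwise_fst_nei
#' @return a `dist_matrix` (or list with p-values when `n_perm > 0`).
#' @export
fst_meirmans <- function(gm, grouping = "site", n_perm = 0, seed = 1L) {
  pairwise_diff_matrix(gm, grouping, "fst_meirmans", n_perm, seed)
}

#' Multilocus Weir-Cockerham theta over all groups
#'
#' Moment-based theta from the gamete-level nested analysis of variance
#' (groups > individuals > gametes), with numerator and denominator components
#' summed over loci. Used as the overall differentiation summary and as the
#' two-level special case of [hierarchical_f()].
#'
#' @param gm a `genotype_matrix`.
#' @param grouping `"site"`, `"ecotope"` or `"site_ecotope"`.
#' @return list with `theta` and the summed variance `components`.
#' @export
wc_theta <- function(gm, grouping = "site") {
  labels <- group_labels(gm, grouping)
  comp <- nested_components(gm$geno, list(group = labels))
  s <- colSums(comp, na.rm = TRUE)
  list(theta = unname(s[1] / sum(s)), components = s)
}
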