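## per-group, per-locus allele counts: list of matrices (groups x loci)
## n_called (diploids with data), alt (alternate-allele copies), ho (obs het)
group_locus_counts <- function(gm, labels) {
  g <- gm$geno
  called <- !is.na(g)
  g0 <- g; g0[!called] <- 0L
  n_called <- rowsum(called + 0, labels)
  alt <- rowsum(g0, labels)
  het <- rowsum((!is.na(g) & g == 1L) + 0, labels)
  list(n = n_called, alt = alt, het = het, groups = rownames(n_called))
}

#' Per-group genetic diversity statistics
#'
#' Observed heterozygosity, Nei's unbiased gene diversity (with the
#' `2n/(2n-1)` small-sample correction), the inbreeding coefficient
#' `F_IS = 1 - H_O / H_E`, and rarefied allelic richness, each averaged over
#' loci with at least two called genotypes in the group.
#'
#' @param gm a `genotype_matrix`.
#' @param grouping `"site"`, `"ecotope"` or `"site_ecotope"`.
#' @param g rarefaction size (gene copies) passed to
#'   [rarefied_allelic_richness()]; `NULL` for its default.
#' @return data.frame with one row per group: `group`, `n`, `ho`, `he`,
#'   `fis`, `ar`.
#' @export
diversity_stats <- function(gm, grouping = "site", g = NULL) {
  labels <- group_labels(gm, grouping)
  sizes <- table(labels)
  if (any(sizes < 2)) {
    stop("group(s) with fewer than 2 samples: ",
         paste(names(sizes)[sizes < 2], collapse = ", "))
  }
  cc <- group_locus_counts(gm, labels)
  ok <- cc$n >= 2
  p <- ifelse(ok, cc$alt / (2 * cc$n), NA)
  ho <- ifelse(ok, cc$het / cc$n, NA)
  he <- ifelse(ok, (2 * cc$n / (2 * cc$n - 1)) * 2 * p * (1 - p), NA)
  ho_bar <- rowMeans(ho, na.rm = TRUE)
  he_bar <- rowMeans(he, na.rm = TRUE)
  fis <- ifelse(he_bar > 0, 1 - ho_bar / he_bar, 0)
  ar <- rarefied_allelic_richness(gm, grouping, g = g)
  data.frame(group = cc$groups, n = as.integer(sizes[cc$groups]),
             ho = ho_bar, he = he_bar, fis = fis,
             ar = ar$ar[match(cc$groups, ar$group)], row.names = NULL)
}

#' Rarefied allelic richness per group
#'
#' Expected number of alleles observed in a random subsample of `g` gene
#' copies: `A_r = sum_i [1 - C(N - N_i, g) / C(N, g)]` over alleles `i`, with
#' `N` called gene copies and `N_i` copies of allele `i`, averaged over loci
#' with at least `g` copies. For biallelic loci `A_r` lies in `[1, 2]`.
#'
#' @param gm a `genotype_matrix`.
#' @param grouping `"site"`, `"ecotope"` or `"site_ecotope"`.
#' @param g rarefaction size in gene copies; default is the smallest
#'   per-locus gene-copy count over all groups (loci with data).
#' @return data.frame with `group`, `ar`, `g`, plus attribute
#'   `"per_locus"` (groups x loci matrix of per-locus richness).
#' @export
rarefied_allelic_richness <- function(gm, grouping = "site", g = NULL) {
  labels <- group_labels(gm, grouping)
  cc <- group_locus_counts(gm, labels)
  copies <- 2 * cc$n
  if (is.null(g)) {
    g <- min(copies[copies > 0])
  }
  if (g < 2) stop("rarefaction size g must be at least 2")
  # allele counts: N_alt = alt, N_ref = copies - alt
  ar <- matrix(NA_real_, nrow(cc$n), ncol(cc$n), dimnames = dimnames(cc$n))
  has <- copies >= g
  N <- copies[has]; Na <- cc$alt[has]; Nr <- N - Na
  miss <- function(Ni) exp(lchoose(N - Ni, g) - lchoose(N, g))
  ar[has] <- (1 - miss(Na)) + (1 - miss(Nr))
  data.frame(group = cc$groups, ar = rowMeans(ar, na.rm = TRUE), g = g,
             row.names = NULL) -> out
  attr(out, "per_locus") <- ar
  out
}

#' Permutation test for a group difference in allelic richness
#'
#' Two-sided permutation two-sample t-test on the per-locus rarefied richness
#' values of two groups; locus values are pooled and group labels permuted.
#'
#' @param gm a `genotype_matrix`.
#' @param group_a,group_b group labels under `grouping`.
#' @param grouping `"site"`, `"ecotope"` or `"site_ecotope"`.
#' @param g rarefaction size (shared by both groups; default as in
#'   [rarefied_allelic_richness()] computed on the two groups).
#' @param n_perm number of permutations (default 10000).
#' @param seed integer seed.
#' @return list with `statistic` (observed mean difference a - b), `p`,
#'   `n_perm`.
#' @export
richness_permutation_test <- function(gm, group_a, group_b,
                                      grouping = "site", g = NULL,
                                      n_perm = 10000, seed = 1L) {
  labels <- group_labels(gm, grouping)
  keep <- labels %in% c(group_a, group_b)
  if (!any(labels == group_a) || !any(labels == group_b)) {
    stop("both groups must be present")
  }
  sub <- subset_genotypes(gm, samples = keep)
  ar <- rarefied_allelic_richness(sub, grouping, g = g)
  per_locus <- attr(ar, "per_locus")
  a <- per_locus[group_a, ]; b <- per_locus[group_b, ]
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  obs <- mean(a) - mean(b)
  pooled <- c(a, b)
  na <- length(a)
  if (stats::sd(pooled) == 0) {
    return(list(statistic = obs, p = 1, n_perm = n_perm))
  }
  hits <- with_seed(seed, {
    sum(vapply(seq_len(n_perm), function(i) {
      idx <- sample.int(length(pooled), na)
      abs(mean(pooled[idx]) - mean(pooled[-idx])) >= abs(obs) - 1e-12
    }, logical(1)))
  })
  list(statistic = obs, p = (hits + 1) / (n_perm + 1), n_perm = n_perm)
}

#' Pairwise linkage-disequilibrium r-squared between loci
#'
#' Composite (Burrows-style) r-squared: the squared Pearson correlation of
#' genotype codes per locus pair over pairwise-complete samples. Monomorphic
#' pairs are undefined, excluded and counted.
#'
#' @param gm a `genotype_matrix`.
#' @param threshold r-squared cutoff for the reported exceedance fraction.
#' @param max_pairs optional cap: if the number of locus pairs exceeds this, a
#'   deterministic systematic subsample of loci is used.
#' @return list with `r2` (pair table), `fraction_above`, `n_excluded`,
#'   `threshold`.
#' @export
ld_r2 <- function(gm, threshold = 0.2, max_pairs = 2e6) {
  g <- gm$geno
  keep <- apply(g, 2, function(x) stats::sd(x, na.rm = TRUE) > 0)
  keep[is.na(keep)] <- FALSE
  n_mono <- sum(!keep)
  g <- g[, keep, drop = FALSE]
  if (ncol(g) < 2) stop("need at least 2 polymorphic loci")
  if (choose(ncol(g), 2) > max_pairs) {
    take <- round(seq(1, ncol(g), length.out = floor(sqrt(2 * max_pairs))))
    g <- g[, unique(take), drop = FALSE]
  }
  cm <- suppressWarnings(stats::cor(g, use = "pairwise.complete.obs"))
  r2 <- cm[lower.tri(cm)]^2
  idx <- which(lower.tri(cm), arr.ind = TRUE)
  tab <- data.frame(locus_a = colnames(g)[idx[, 2]],
                    locus_b = colnames(g)[idx[, 1]], r2 = r2)
  n_undef <- sum(is.na(r2))
  list(r2 = tab, fraction_above = mean(r2 > threshold, na.rm = TRUE),
       n_excluded = n_mono + n_undef, threshold = threshold)
}
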