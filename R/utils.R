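#' Derive a per-stage substream seed from a global seed
#'
#' Every stochastic stage of the pipeline draws its own seed from the single
#' global seed through this splitting rule, so any stage can be re-run in
#' isolation and reproduce exactly what it did inside a full pipeline run.
#' The rule is `(seed * 48271 + stage_offset) mod (2^31 - 1)`: a single step
#' of the Lehmer (MINSTD) generator offset by a stage index, which keeps the
#' result a valid 32-bit integer seed and makes distinct stages decorrelated.
#'
#' @param seed integer global seed.
#' @param stage integer stage offset (each named pipeline stage has a fixed one).
#' @return an integer seed.
#' @export
substream_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.numeric(stage))
  m <- 2147483647
  as.integer((abs(seed) %% m * 48271 + stage) %% m)
}

## run code with a private RNG state, restoring the caller's stream
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}

#' Labelled symmetric distance matrix
#'
#' Light container used for every pairwise matrix in the package (genetic,
#' geographic, effective/commute). Validates symmetry, a zero diagonal and
#' finiteness, and keeps a `kind` tag so downstream code can refuse to mix
#' incompatible matrices.
#'
#' @param values square numeric matrix.
#' @param labels character vector of group labels (defaults to dimnames).
#' @param kind one of `"fst_nei"`, `"gst_hedrick"`, `"fst_meirmans"`,
#'   `"geographic_km"`, `"effective"`, `"euclidean_allele"`, `"other"`.
#' @param tol numeric tolerance for the symmetry/zero-diagonal checks.
#' @return an object of class `dist_matrix` (a matrix with attributes).
#' @export
dist_matrix <- function(values, labels = NULL, kind = "other", tol = 1e-8) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("distance matrix must be square")
  if (is.null(labels)) labels <- rownames(values)
  if (is.null(labels)) labels <- as.character(seq_len(nrow(values)))
  if (length(labels) != nrow(values)) stop("labels do not match matrix size")
  if (any(!is.finite(values))) stop("distance matrix contains non-finite values")
  if (max(abs(values - t(values))) > tol) stop("distance matrix is not symmetric")
  if (max(abs(diag(values))) > tol) stop("distance matrix diagonal is not zero")
  values <- (values + t(values)) / 2
  diag(values) <- 0
  dimnames(values) <- list(labels, labels)
  structure(values, class = c("dist_matrix", "matrix"), kind = kind)
}

#' @export
print.dist_matrix <- function(x, ...) {
  cat(sprintf("dist_matrix (%s), %d labels\n", attr(x, "kind"), nrow(x)))
  print(unclass(x)[seq_len(min(6L, nrow(x))), seq_len(min(6L, ncol(x))), drop = FALSE])
  invisible(x)
}

## lower-triangle values in a fixed (column-major) order
lower_tri <- function(m) m[lower.tri(m)]

## align a dist_matrix to a label order, error on mismatch
align_dm <- function(dm, labels) {
  if (!all(labels %in% rownames(dm))) {
    stop("distance matrix is missing labels: ",
         paste(setdiff(labels, rownames(dm)), collapse = ", "))
  }
  dist_matrix(unclass(dm)[labels, labels, drop = FALSE], labels,
              kind = attr(dm, "kind"))
}

#' Correlation between two distance matrices
#'
#' Pearson correlation of the lower triangles of two labelled matrices, with a
#' Mantel-style permutation p-value (rows and columns of the second matrix are
#' permuted jointly).
#'
#' @param dm_a,dm_b `dist_matrix` objects over the same labels.
#' @param n_perm number of permutations for the p-value.
#' @param seed integer seed for the permutations.
#' @return list with `r`, `r_squared`, `p` (two-sided permutation p), `n_pairs`.
#' @export
matrix_correlation <- function(dm_a, dm_b, n_perm = 9999, seed = 1L) {
  dm_b <- align_dm(dm_b, rownames(dm_a))
  a <- lower_tri(unclass(dm_a)); b <- lower_tri(unclass(dm_b))
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    return(list(r = NA_real_, r_squared = NA_real_, p = NA_real_,
                n_pairs = length(a), note = "constant matrix"))
  }
  r <- stats::cor(a, b)
  n <- nrow(dm_a)
  bmat <- unclass(dm_b)
  hits <- with_seed(seed, {
    sum(vapply(seq_len(n_perm), function(i) {
      idx <- sample.int(n)
      abs(stats::cor(a, lower_tri(bmat[idx, idx]))) >= abs(r) - 1e-12
    }, logical(1)))
  })
  list(r = r, r_squared = r^2, p = (hits + 1) / (n_perm + 1), n_pairs = length(a))
}

## Benjamini-Hochberg across a symmetric p matrix's lower triangle
adjust_p_matrix <- function(p_mat) {
  p <- p_mat[lower.tri(p_mat)]
  q <- stats::p.adjust(p, method = "BH")
  out <- p_mat
  out[lower.tri(out)] <- q
  out[upper.tri(out)] <- t(out)[upper.tri(out)]
  out
}
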