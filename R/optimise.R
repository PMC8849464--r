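#' Small-sample corrected Akaike information criterion
#'
#' `AICc = -2 logLik + 2k + 2k(k+1)/(n - k - 1)`.
#'
#' @param logLik model log-likelihood.
#' @param k parameter count (surface parameters plus the intercept).
#' @param n effective sample size; by convention the number of sites.
#' @return the AICc value.
#' @export
aicc <- function(logLik, k, n) {
  if (n <= k + 1) stop("n must exceed k + 1: model too complex for the sample")
  -2 * logLik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' AICc model-selection table
#'
#' @param models list of fitted surface models (from [ga_optimise()],
#'   [distance_model()], [null_model()]), each with `name`, `type`, `k`,
#'   `aicc`.
#' @return data.frame sorted by AICc with `delta_aicc` and Akaike weights
#'   `weight` (normalised `exp(-delta/2)`).
#' @export
model_selection <- function(models) {
  tab <- data.frame(
    model = vapply(models, `[[`, character(1), "name"),
    type = vapply(models, `[[`, character(1), "type"),
    k = vapply(models, function(m) as.numeric(m$k), numeric(1)),
    aicc = vapply(models, function(m) as.numeric(m$aicc), numeric(1)))
  tab <- tab[order(tab$aicc), ]
  tab$delta_aicc <- tab$aicc - tab$aicc[1]
  w <- exp(-tab$delta_aicc / 2)
  tab$weight <- w / sum(w)
  rownames(tab) <- NULL
  tab
}

## fast MLPE of genetic distance on one standardised predictor; shared by the
## GA objective and the model constructors. pair_idx is the lower-triangle
## index pair matrix; Z the pair-population incidence.
surface_mlpe <- function(x_lower, y_lower, Z) {
  x <- (x_lower - mean(x_lower)) / stats::sd(x_lower)
  W <- cbind(`(Intercept)` = 1, xdist = x)
  mlpe_profile_fit(y_lower, W, Z)
}

make_pair_structure <- function(genetic_dm) {
  n <- nrow(genetic_dm)
  idx <- which(lower.tri(unclass(genetic_dm)), arr.ind = TRUE)
  m <- nrow(idx)
  Z <- matrix(0, m, n)
  Z[cbind(seq_len(m), idx[, 1])] <- 1
  Z[cbind(seq_len(m), idx[, 2])] <- 1
  list(y = unclass(genetic_dm)[idx], Z = Z, idx = idx,
       labels = rownames(genetic_dm))
}

#' Fit the MLPE model of genetic distance on an effective-distance matrix
#'
#' The predictor is standardised to zero mean and unit SD over pairs before
#' fitting, so model likelihoods are comparable across surfaces of different
#' resistance scales.
#'
#' @param effective_dm predictor `dist_matrix` (commute/effective distances).
#' @param genetic_dm response `dist_matrix` (e.g. Hedrick G''ST).
#' @return an `mlpe` fit.
#' @export
fit_surface_model <- function(effective_dm, genetic_dm) {
  pairs <- pair_table(genetic_dm, effective_dm)
  pairs$xdist <- (pairs$xdist_raw - mean(pairs$xdist_raw)) /
    stats::sd(pairs$xdist_raw)
  mlpe(gdist ~ xdist, pairs)
}

#' Precompute a fast commute-distance evaluator for a fixed landscape
#'
#' Fixes the graph topology (valid cells, neighbour structure, focal nodes,
#' sparse Cholesky pattern) once, so that repeated evaluations with different
#' cell resistances — as in the genetic-algorithm search — only update edge
#' conductances and re-factorise numerically.
#'
#' @param template a `raster_surface` fixing dimensions and nodata pattern.
#' @param sites data.frame with `site_id`, `x`, `y`.
#' @param connectivity 4 or 8.
#' @return a function `(values_matrix) -> dist_matrix` of commute distances.
#' @export
make_commute_evaluator <- function(template, sites, connectivity = 8) {
  tmpl <- raster_surface(ifelse(is.na(template$values), NA, 1),
                         template$cell_size, template$origin)
  graph <- build_conductance_graph(tmpl, connectivity)
  focal <- site_nodes(graph, sites)
  comp <- graph_component_of(graph)
  if (length(unique(comp[focal])) > 1) {
    stop("focal sites fall in disconnected components")
  }
  if (any(comp != comp[focal[1]])) {
    stop("template has valid cells outside the focal component; mask them")
  }
  e <- graph$edges
  cells <- graph$cells
  lin_a <- cells[e$a, 1] + (cells[e$a, 2] - 1) * graph$dim[1]
  lin_b <- cells[e$b, 1] + (cells[e$b, 2] - 1) * graph$dim[1]
  dmul <- ifelse(abs(cells[e$a, 1] - cells[e$b, 1]) +
                   abs(cells[e$a, 2] - cells[e$b, 2]) == 2, sqrt(2), 1)
  n <- graph$n_nodes
  ground <- focal[length(focal)]
  idx <- setdiff(seq_len(n), ground)
  ij <- cbind(c(e$a, e$b, seq_len(n)), c(e$b, e$a, seq_len(n)))
  build_L <- function(cond) {
    deg <- rowsum_vec(e$a, cond, n) + rowsum_vec(e$b, cond, n)
    Matrix::sparseMatrix(i = ij[, 1], j = ij[, 2],
                         x = c(-cond, -cond, deg), dims = c(n, n))
  }
  ch <- Matrix::Cholesky(Matrix::forceSymmetric(build_L(rep(1, nrow(e)))[idx, idx]),
                         LDL = FALSE, perm = TRUE)
  rhs_pos <- match(focal[-length(focal)], idx)
  rhs <- Matrix::sparseMatrix(i = rhs_pos, j = seq_along(rhs_pos), x = 1,
                              dims = c(length(idx), length(rhs_pos)))
  labels <- names(focal)
  mpos <- c(rhs_pos, NA)                     # focal rows in the reduced system
  function(values) {
    res <- (values[lin_a] + values[lin_b]) / 2 * dmul
    cond <- 1 / res
    L <- build_L(cond)
    ch2 <- Matrix::update(ch, Matrix::forceSymmetric(L[idx, idx]))
    Xg <- as.matrix(Matrix::solve(ch2, rhs, system = "A"))
    nf <- length(focal)
    Xf <- matrix(0, nf, nf)
    Xf[seq_len(nf - 1), seq_len(nf - 1)] <- Xg[rhs_pos, , drop = FALSE]
    reff <- outer(diag(Xf), diag(Xf), `+`) - Xf - t(Xf)
    diag(reff) <- 0
    vol <- 2 * sum(cond)
    dist_matrix(vol * reff, labels, kind = "effective")
  }
}

## --- parameter encoding for the GA ------------------------------------------

## bounds and decoding per surface; continuous surfaces have genes
## (variant, log shape, log(max - 1)); categorical surfaces one log-resistance
## gene per non-anchor class
surface_genes <- function(surface) {
  if (surface$type == "continuous") {
    data.frame(gene = c("variant", "log_shape", "log_maxm1"),
               lo = c(0.5 + 1e-9, log(0.01), log(0.5)),
               hi = c(8.5 - 1e-9, log(10), log(99)))
  } else {
    cls <- setdiff(surface$raster$classes, surface$anchor_class)
    data.frame(gene = paste0("class_", cls),
               lo = rep(log(1), length(cls)), hi = rep(log(100), length(cls)))
  }
}

decode_surface <- function(surface, genes) {
  if (surface$type == "continuous") {
    list(variant = as.integer(round(genes[1])),
         shape = exp(genes[2]), max_resistance = 1 + exp(genes[3]))
  } else {
    cls <- setdiff(surface$raster$classes, surface$anchor_class)
    vals <- c(1, exp(genes))
    names(vals) <- c(surface$anchor_class, cls)
    list(class_values = vals)
  }
}

surface_resistance <- function(surface, params) {
  if (surface$type == "continuous") {
    monomolecular(surface$raster, params$variant, params$shape,
                  params$max_resistance)$values
  } else {
    cv <- params$class_values
    reclassify_surface(surface$raster,
                       cv[order(as.numeric(names(cv)))])$values
  }
}

## composite resistance: cell-wise sum, re-anchored to minimum 1
combine_resistance <- function(value_list) {
  v <- Reduce(`+`, value_list)
  v - min(v, na.rm = TRUE) + 1
}

#' Optimise resistance-surface parameters with a genetic algorithm
#'
#' Real-coded GA over the transform parameters of one or more surfaces
#' (continuous: monomolecular variant, shape and maximum; categorical:
#' per-class resistance with the anchor class fixed at 1). Each candidate is
#' scored by the log-likelihood of the MLPE fit of the genetic distances on
#' the commute-time effective distances of the candidate resistance surface.
#' Composite candidates sum component resistances cell-wise and re-anchor the
#' minimum to 1. Tournament selection, blend (BLX-alpha) crossover, Gaussian
#' mutation, one-elite survival, and a patience-based stop.
#'
#' @param surfaces named list; each element a list with `raster` (continuous
#'   rasters already rescaled to `[1, 100]`), `type` (`"continuous"` or
#'   `"categorical"`), and for categorical surfaces `anchor_class`.
#' @param genetic_dm response `dist_matrix` over sites.
#' @param sites data.frame with `site_id`, `x`, `y` matching `genetic_dm`.
#' @param ga_config list overriding defaults: `pop_mult` (20), `generations`
#'   (50), `patience` (10), `p_crossover` (0.8), `p_mutation` (0.2),
#'   `mutation_sd` (0.15 of each gene range), `blx_alpha` (0.5), `seed`.
#' @param n_aicc effective sample size for the reported AICc (default: number
#'   of sites).
#' @return a surface model: list with `name`, `type`, `k`, `params`,
#'   `logLik`, `aicc`, `fit` (coefficients etc.), `effective_dm`,
#'   `resistance` (a `raster_surface`), `converged`, `trace`.
#' @export
ga_optimise <- function(surfaces, genetic_dm, sites, ga_config = list(),
                        n_aicc = nrow(genetic_dm)) {
  cfg <- utils::modifyList(
    list(pop_mult = 20, generations = 50, patience = 10, p_crossover = 0.8,
         p_mutation = 0.2, mutation_sd = 0.15, blx_alpha = 0.5, seed = 1L),
    ga_config)
  stopifnot(length(surfaces) >= 1)
  if (is.null(names(surfaces))) names(surfaces) <- paste0("s", seq_along(surfaces))
  genetic_dm <- align_dm(genetic_dm, as.character(sites$site_id))
  gene_tab <- lapply(surfaces, surface_genes)
  n_genes <- vapply(gene_tab, nrow, integer(1))
  lo <- unlist(lapply(gene_tab, `[[`, "lo"), use.names = FALSE)
  hi <- unlist(lapply(gene_tab, `[[`, "hi"), use.names = FALSE)
  d <- length(lo)
  ps <- make_pair_structure(genetic_dm)
  evalc <- make_commute_evaluator(surfaces[[1]]$raster, sites)

  decode_all <- function(g) {
    split_g <- split(g, rep(seq_along(surfaces), n_genes))
    mapply(decode_surface, surfaces, split_g, SIMPLIFY = FALSE)
  }
  objective <- function(g) {
    params <- decode_all(g)
    vals <- combine_resistance(mapply(surface_resistance, surfaces, params,
                                      SIMPLIFY = FALSE))
    eff <- evalc(vals)
    surface_mlpe(lower_tri(unclass(eff)), ps$y, ps$Z)$logLik
  }

  pop_size <- max(cfg$pop_mult * d, 10)
  best <- with_seed(cfg$seed, {
    pop <- matrix(stats::runif(pop_size * d, lo, hi), pop_size, d, byrow = TRUE)
    fit <- apply(pop, 1, objective)
    trace <- max(fit)
    best_g <- pop[which.max(fit), ]; best_f <- max(fit)
    stall <- 0L; gen_used <- 0L
    for (gen in seq_len(cfg$generations)) {
      gen_used <- gen
      # tournament selection (size 2)
      pick <- function() {
        i <- sample.int(pop_size, 2)
        i[which.max(fit[i])]
      }
      new_pop <- matrix(0, pop_size, d)
      new_pop[1, ] <- best_g                       # elitism
      for (k in seq(2, pop_size)) {
        a <- pop[pick(), ]; b <- pop[pick(), ]
        child <- if (stats::runif(1) < cfg$p_crossover) {
          # BLX-alpha blend
          cmin <- pmin(a, b); cmax <- pmax(a, b); rng <- cmax - cmin
          stats::runif(d, cmin - cfg$blx_alpha * rng,
                       cmax + cfg$blx_alpha * rng)
        } else a
        mut <- stats::runif(d) < cfg$p_mutation
        child[mut] <- child[mut] +
          stats::rnorm(sum(mut), 0, cfg$mutation_sd * (hi - lo)[mut])
        new_pop[k, ] <- pmin(pmax(child, lo), hi)
      }
      pop <- new_pop
      fit <- apply(pop, 1, objective)
      if (max(fit) > best_f + 1e-6) {
        best_f <- max(fit); best_g <- pop[which.max(fit), ]; stall <- 0L
      } else stall <- stall + 1L
      trace <- c(trace, best_f)
      if (stall >= cfg$patience) break
    }
    list(g = best_g, f = best_f, trace = trace,
         converged = stall < cfg$patience, generations = gen_used)
  })

  params <- decode_all(best$g)
  vals <- combine_resistance(mapply(surface_resistance, surfaces, params,
                                    SIMPLIFY = FALSE))
  eff <- evalc(vals)
  fit <- surface_mlpe(lower_tri(unclass(eff)), ps$y, ps$Z)
  k <- sum(vapply(surfaces, function(s)
    if (s$type == "continuous") 3 else length(s$raster$classes),
    numeric(1))) + 1
  resistance <- raster_surface(
    matrix(vals, nrow(surfaces[[1]]$raster$values)),
    surfaces[[1]]$raster$cell_size, surfaces[[1]]$raster$origin)
  list(name = paste(names(surfaces), collapse = " + "),
       type = if (length(surfaces) > 1) "composite" else "single",
       k = k, params = params, logLik = fit$logLik,
       aicc = aicc(fit$logLik, k, n_aicc), fit = fit,
       effective_dm = eff, resistance = resistance,
       converged = best$converged, trace = best$trace)
}

#' Distance-only (isolation-by-distance) reference model
#'
#' All-ones resistance: the predictor reduces to straight-line geographic
#' distance. `k = 2` (slope + intercept).
#'
#' @param genetic_dm response `dist_matrix`.
#' @param sites site table with coordinates.
#' @param n_aicc effective sample size (default number of sites).
#' @return a surface model list (as [ga_optimise()]).
#' @export
distance_model <- function(genetic_dm, sites, n_aicc = nrow(genetic_dm)) {
  genetic_dm <- align_dm(genetic_dm, as.character(sites$site_id))
  geo <- geographic_distances(sites)
  ps <- make_pair_structure(genetic_dm)
  fit <- surface_mlpe(lower_tri(unclass(geo)), ps$y, ps$Z)
  list(name = "distance", type = "single", k = 2, params = NULL,
       logLik = fit$logLik, aicc = aicc(fit$logLik, 2, n_aicc), fit = fit,
       effective_dm = geo, resistance = NULL, converged = TRUE)
}

#' Intercept-only null model
#'
#' @inheritParams distance_model
#' @return a surface model list (as [ga_optimise()]).
#' @export
null_model <- function(genetic_dm, sites = NULL, n_aicc = nrow(genetic_dm)) {
  ps <- make_pair_structure(genetic_dm)
  fit <- mlpe_profile_fit(ps$y, matrix(1, length(ps$y), 1,
                                       dimnames = list(NULL, "(Intercept)")),
                          ps$Z)
  list(name = "null", type = "single", k = 1, params = NULL,
       logLik = fit$logLik, aicc = aicc(fit$logLik, 1, n_aicc), fit = fit,
       effective_dm = NULL, resistance = NULL, converged = TRUE)
}

#' Bootstrap ranking of fitted surface models
#'
#' Repeatedly subsamples a fraction of the sites (without replacement),
#' refits each model's MLPE on the sub-matrix of its cached effective
#' distances (surface parameters frozen at their full-data optima),
#' recomputes AICc with the subsample size, and records model ranks.
#'
#' @param models list of fitted surface models (must include their
#'   `effective_dm`; the null model competes with its intercept-only fit).
#' @param sites full site table.
#' @param genetic_dm response `dist_matrix`.
#' @param frac fraction of sites per iteration (default 0.85).
#' @param n_boot iterations (default 500).
#' @param seed integer seed.
#' @return data.frame per model: `model`, `k`, `avg_aicc`, `avg_rank`,
#'   `top_pct`; attribute `"n_used"` gives iterations retained.
#' @export
bootstrap_rank <- function(models, sites, genetic_dm, frac = 0.85,
                           n_boot = 500, seed = 1L) {
  n <- nrow(sites)
  n_sub <- ceiling(frac * n)
  if (n_sub < 4) stop("subsample too small: frac * n_sites must be >= 4")
  labels <- as.character(sites$site_id)
  genetic_dm <- align_dm(genetic_dm, labels)
  M <- length(models)
  nm <- vapply(models, `[[`, character(1), "name")
  ranks <- matrix(NA_real_, n_boot, M)
  aiccs <- matrix(NA_real_, n_boot, M)
  with_seed(seed, {
    for (b in seq_len(n_boot)) {
      sub <- sort(sample.int(n, n_sub))
      labs <- labels[sub]
      g_sub <- dist_matrix(unclass(genetic_dm)[labs, labs], labs)
      ps <- make_pair_structure(g_sub)
      a <- vapply(models, function(mod) {
        if (is.null(mod$effective_dm)) {
          fit <- mlpe_profile_fit(ps$y,
                                  matrix(1, length(ps$y), 1,
                                         dimnames = list(NULL, "(Intercept)")),
                                  ps$Z)
        } else {
          x <- lower_tri(unclass(align_dm(mod$effective_dm, labs)))
          fit <- surface_mlpe(x, ps$y, ps$Z)
        }
        if (n_sub <= mod$k + 1) return(NA_real_)
        aicc(fit$logLik, mod$k, n_sub)
      }, numeric(1))
      aiccs[b, ] <- a
      ranks[b, ] <- rank(a, ties.method = "min", na.last = "keep")
    }
  })
  used <- stats::complete.cases(aiccs)
  out <- data.frame(model = nm,
                    k = vapply(models, function(m) as.numeric(m$k), numeric(1)),
                    avg_aicc = colMeans(aiccs[used, , drop = FALSE]),
                    avg_rank = colMeans(ranks[used, , drop = FALSE]),
                    top_pct = 100 * colMeans(
                      ranks[used, , drop = FALSE] == 1, na.rm = TRUE))
  out <- out[order(-out$top_pct, out$avg_rank), ]
  rownames(out) <- NULL
  attr(out, "n_used") <- sum(used)
  out
}
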