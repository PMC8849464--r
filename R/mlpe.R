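#' Fit a GLS regression with MLPE correlation structure
#'
#' Regression for pairwise distance data. Each observation is an unordered
#' pair of populations; observations sharing a population are correlated. The
#' model is \deqn{Y = W\theta + \epsilon, \quad
#'   Var(\epsilon) = \sigma^2_e I + \sigma^2_u Z Z^\top}
#' where `Z` is the pairs-by-populations incidence matrix with a 1 for each of
#' the two populations of a pair (the "maximum likelihood population effects"
#' structure). The pair-correlation parameter reported is
#' `rho = sigma2_u / (2 * sigma2_u + sigma2_e)`, which lies in `[0, 0.5)`.
#'
#' The variance ratio `phi = sigma2_u / sigma2_e` is profiled out by a 1-D
#' likelihood search on the log scale over `[1e-8, 1e3]`; at each candidate the
#' GLS solution is computed through the Woodbury identity (populations are few,
#' pairs are many). Maximum likelihood is the default objective so that fits
#' are comparable across fixed-effect structures (AICc model selection);
#' REML is available for variance estimation.
#'
#' @param formula model formula in the columns of `data`, e.g.
#'   `gdist ~ xdist` or `gdist ~ xdist * ecotope`.
#' @param data data.frame of pairs containing the formula variables plus the
#'   two population labels of each pair.
#' @param pops character length-2: names of the two population-label columns
#'   (default `c("pop1", "pop2")`).
#' @param reml logical; if `TRUE` use the REML criterion.
#' @return an object of class `mlpe` with components `coefficients`, `vcov`,
#'   `sigma2_e`, `sigma2_u`, `rho`, `logLik`, `k` (number of fixed-effect
#'   coefficients incl. intercept), `n_pairs`, `n_pops`, `fitted`,
#'   `residuals`, and the model frame for refitting.
#' @examples
#' d <- data.frame(pop1 = c("a","a","a","b","b","c"),
#'                 pop2 = c("b","c","d","c","d","d"),
#'                 xdist = c(1, 2, 3, 1.5, 2.5, 1), gdist = rnorm(6))
#' fit <- mlpe(gdist ~ xdist, d)
#' coef(fit)
#' @export
mlpe <- function(formula, data, pops = c("pop1", "pop2"), reml = FALSE) {
  if (!all(pops %in% names(data))) {
    stop("population label columns not found: ", paste(pops, collapse = ", "))
  }
  mf <- stats::model.frame(formula, data, na.action = stats::na.fail)
  Y <- stats::model.response(mf)
  W <- stats::model.matrix(attr(mf, "terms"), mf)
  if (qr(W)$rank < ncol(W)) {
    stop("singular design matrix; check that every stratum/term has data")
  }
  p1 <- as.character(data[[pops[1]]]); p2 <- as.character(data[[pops[2]]])
  if (any(p1 == p2)) stop("self-pairs (i == j) are not allowed")
  groups <- sort(unique(c(p1, p2)))
  if (length(groups) < 3) stop("need at least 3 populations")
  m <- length(Y)
  Z <- matrix(0, m, length(groups))
  Z[cbind(seq_len(m), match(p1, groups))] <- 1
  Z[cbind(seq_len(m), match(p2, groups))] <- 1

  # centre non-intercept columns internally for numerical stability; map the
  # intercept and its covariance back afterwards (predictor centring must not
  # leak into the reported slopes)
  Y <- unname(Y)
  has_int <- "(Intercept)" %in% colnames(W)
  mu <- if (has_int) colMeans(W) else rep(0, ncol(W))
  if (has_int) mu[colnames(W) == "(Intercept)"] <- 0
  Wc <- sweep(W, 2, mu)
  core <- mlpe_profile_fit(Y, Wc, Z, reml = reml)
  if (has_int && any(mu != 0)) {
    A <- diag(ncol(W))
    dimnames(A) <- list(colnames(W), colnames(W))
    A["(Intercept)", ] <- -mu
    A["(Intercept)", "(Intercept)"] <- 1
    core$theta <- as.numeric(A %*% core$theta)
    core$vcov <- A %*% core$vcov %*% t(A)
  }

  fitted <- as.numeric(W %*% core$theta)
  structure(list(coefficients = stats::setNames(core$theta, colnames(W)),
                 vcov = core$vcov, sigma2_e = core$sigma2_e,
                 sigma2_u = core$sigma2_u, rho = core$rho,
                 logLik = core$logLik, k = ncol(W),
                 n_pairs = m, n_pops = length(groups),
                 fitted = fitted, residuals = Y - fitted,
                 formula = formula, data = data, pops = pops, reml = reml,
                 Z = Z, W = W, y = Y, groups = groups),
            class = "mlpe")
}

## profile likelihood over the variance ratio; shared by mlpe() and the fast
## surface-fitting path. Returns coefficients, variances and the log-likelihood.
mlpe_profile_fit <- function(Y, W, Z, reml = FALSE) {
  m <- length(Y); p <- ncol(W)
  G <- crossprod(Z)                       # n x n, n populations
  eg <- eigen(G, symmetric = TRUE)
  lam <- pmax(eg$values, 0)
  Q <- eg$vectors
  ZtY <- crossprod(Z, Y); ZtW <- crossprod(Z, W)
  QtZtY <- crossprod(Q, ZtY); QtZtW <- crossprod(Q, ZtW)

  eval_phi <- function(log_phi) {
    phi <- exp(log_phi)
    w <- phi / (1 + phi * lam)            # V^-1 = I - Z Q diag(w) Q' Z'
    # V^-1 applied through the low-rank correction
    WtViW <- crossprod(W) - crossprod(QtZtW, QtZtW * w)
    WtViY <- crossprod(W, Y) - crossprod(QtZtW, QtZtY * w)
    YtViY <- sum(Y^2) - sum(w * QtZtY^2)
    R <- chol(WtViW)
    theta <- backsolve(R, backsolve(R, WtViY, transpose = TRUE))
    rss <- as.numeric(YtViY - crossprod(WtViY, theta))
    rss <- max(rss, 1e-300)
    ldV <- sum(log1p(phi * lam))
    if (reml) {
      s2 <- rss / (m - p)
      ll <- -0.5 * ((m - p) * log(2 * pi * s2) + ldV +
                      2 * sum(log(diag(R))) + (m - p))
    } else {
      s2 <- rss / m
      ll <- -0.5 * (m * log(2 * pi * s2) + ldV + m)
    }
    list(ll = ll, theta = as.numeric(theta), s2 = s2, R = R, phi = phi)
  }

  opt <- stats::optimize(function(t) -eval_phi(t)$ll,
                         interval = log(c(1e-8, 1e3)), tol = 1e-8)
  # the optimum can sit on the lower boundary (independent pairs)
  cand <- c(opt$minimum, log(1e-8))
  lls <- vapply(cand, function(t) eval_phi(t)$ll, numeric(1))
  best <- eval_phi(cand[which.max(lls)])

  Rinv <- backsolve(best$R, diag(ncol(W)))
  vcov <- best$s2 * tcrossprod(Rinv)
  dimnames(vcov) <- list(colnames(W), colnames(W))
  phi <- best$phi
  list(theta = best$theta, vcov = vcov, sigma2_e = best$s2,
       sigma2_u = phi * best$s2, rho = phi / (2 * phi + 1),
       logLik = best$ll)
}

#' @export
print.mlpe <- function(x, ...) {
  cat("MLPE pairwise regression (", if (x$reml) "REML" else "ML", ")\n", sep = "")
  cat(sprintf("  %d pairs over %d populations; rho = %.4f, sigma2_e = %.3g\n",
              x$n_pairs, x$n_pops, x$rho, x$sigma2_e))
  cat("  logLik:", format(x$logLik, digits = 6), " k:", x$k, "\n")
  cat("Coefficients:\n")
  print(x$coefficients)
  invisible(x)
}

#' @export
summary.mlpe <- function(object, ...) {
  se <- sqrt(diag(object$vcov))
  z <- object$coefficients / se
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = se,
               `z value` = z, `Pr(>|z|)` = 2 * stats::pnorm(-abs(z)))
  out <- list(coefficients = tab, rho = object$rho,
              sigma2_e = object$sigma2_e, sigma2_u = object$sigma2_u,
              logLik = object$logLik, n_pairs = object$n_pairs,
              n_pops = object$n_pops, reml = object$reml)
  class(out) <- "summary.mlpe"
  out
}

#' @export
print.summary.mlpe <- function(x, ...) {
  cat("MLPE pairwise regression (", if (x$reml) "REML" else "ML", ")\n", sep = "")
  stats::printCoefmat(x$coefficients, P.values = TRUE, has.Pvalue = TRUE)
  cat(sprintf("\nrho = %.4f  sigma2_e = %.4g  sigma2_u = %.4g\n",
              x$rho, x$sigma2_e, x$sigma2_u))
  cat(sprintf("logLik = %.4f on %d pairs over %d populations\n",
              x$logLik, x$n_pairs, x$n_pops))
  invisible(x)
}

#' @export
coef.mlpe <- function(object, ...) object$coefficients

#' @export
vcov.mlpe <- function(object, ...) object$vcov

#' @export
logLik.mlpe <- function(object, ...) {
  structure(object$logLik, df = object$k + 2, nobs = object$n_pairs,
            class = "logLik")
}

#' @export
fitted.mlpe <- function(object, ...) object$fitted

#' @export
residuals.mlpe <- function(object, ...) object$residuals

#' @export
predict.mlpe <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  tt <- stats::delete.response(stats::terms(object$formula))
  W <- stats::model.matrix(tt, stats::model.frame(tt, newdata))
  as.numeric(W %*% object$coefficients)
}

#' @export
simulate.mlpe <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  m <- object$n_pairs
  Sigma <- object$sigma2_e * diag(m) + object$sigma2_u * tcrossprod(object$Z)
  L <- t(chol(Sigma))
  out <- as.data.frame(
    object$fitted + L %*% matrix(stats::rnorm(m * nsim), m, nsim))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Likelihood-ratio comparison of nested MLPE fits
#'
#' @param object,... two `mlpe` fits of the same data (reduced first or last).
#' @return data.frame with logLik, df and the chi-square LRT p-value.
#' @export
anova.mlpe <- function(object, ...) {
  fits <- c(list(object), list(...))
  if (length(fits) != 2) stop("supply exactly two mlpe fits to compare")
  if (any(vapply(fits, function(f) f$reml, logical(1)))) {
    stop("likelihood-ratio comparison requires ML fits (reml = FALSE)")
  }
  ord <- order(vapply(fits, function(f) f$k, numeric(1)))
  fits <- fits[ord]
  lr <- 2 * (fits[[2]]$logLik - fits[[1]]$logLik)
  df <- fits[[2]]$k - fits[[1]]$k
  data.frame(model = c("reduced", "full"),
             k = c(fits[[1]]$k, fits[[2]]$k),
             logLik = c(fits[[1]]$logLik, fits[[2]]$logLik),
             LR = c(NA, lr), df = c(NA, df),
             p = c(NA, stats::pchisq(max(lr, 0), df, lower.tail = FALSE)))
}

#' Test the ecotope difference in distance-decay slopes
#'
#' Wald test on the stratum-by-distance interaction coefficient of an MLPE
#' fit, plus a likelihood-ratio test against the fit without the interaction.
#'
#' @param fit an `mlpe` fit whose formula contains an interaction between the
#'   (centred) predictor distance and a two-level stratum factor.
#' @return list with `delta_beta`, `se`, `p_wald`, `p_lrt`.
#' @export
slope_contrast <- function(fit) {
  cn <- names(fit$coefficients)
  int <- grep(":", cn, fixed = TRUE, value = TRUE)
  tl <- attr(stats::terms(fit$formula), "term.labels")
  int_term <- tl[grepl(":", tl, fixed = TRUE)]
  if (length(int) != 1 || length(int_term) != 1) {
    stop("fit must contain exactly one interaction term (stratum x distance)")
  }
  est <- fit$coefficients[[int]]
  se <- sqrt(fit$vcov[int, int])
  # reduced model: drop the interaction
  red_formula <- stats::update(fit$formula, paste(". ~ . -", int_term))
  red <- mlpe(red_formula, fit$data, pops = fit$pops, reml = FALSE)
  lr <- 2 * (fit$logLik - red$logLik)
  list(delta_beta = est, se = se,
       p_wald = 2 * stats::pnorm(-abs(est / se)),
       p_lrt = stats::pchisq(max(lr, 0), fit$k - red$k, lower.tail = FALSE))
}
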