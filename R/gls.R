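# Core generalized-least-squares engine, computed on cell means.
#
# Under the mixed model y_kti = beta_t + theta*Z_kt + gamma_kt + eps_kti the
# covariance of the cell means within cluster k is
#   cov(ybar_ks, ybar_kt) = sigma2 * [ rho*Gamma_st + (1-rho)*delta_st/(N*pi_kt) ].
# Working in the scaled metric V = c*Gamma + diag(1/pi) with c = N*rho/(1-rho),
# the GLS information matrix for (beta, theta) is X' V^-1 X accumulated over
# independent clusters, and var(theta_hat) = sigma2*(1-rho)/N * [(X'V^-1X)^-1]_theta.
# Only the ratio c enters the coefficients, which is why allocations and
# efficiencies depend on (N, rho) only through N*rho/(1-rho).
#
# `cells` is layout$cells restricted to the support; `pi` the matching
# proportions. Epochs with no occupied cell contribute no fixed-effect
# column; an epoch occupied on one arm only forces its coefficients to the
# balance constraint automatically.
gls_engine <- function(cells, pi, Gamma, c_ratio, rcond_tol = 1e-10) {
  n <- nrow(cells)
  eps <- sort(unique(cells$t))
  p <- length(eps) + 1L
  X <- matrix(0, n, p)
  for (j in seq_along(eps)) X[cells$t == eps[j], j] <- 1
  X[, p] <- cells$Z
  M <- matrix(0, p, p)
  W <- vector("list", 0L)
  for (idx in split(seq_len(n), cells$k)) {
    tt <- cells$t[idx]
    V <- c_ratio * Gamma[tt, tt, drop = FALSE] + diag(1 / pi[idx], length(idx))
    R <- tryCatch(chol(V), error = function(e)
      stop("cell-mean covariance is not positive definite", call. = FALSE))
    Wk <- backsolve(R, backsolve(R, X[idx, , drop = FALSE], transpose = TRUE))
    M <- M + crossprod(X[idx, , drop = FALSE], Wk)
    W[[length(W) + 1L]] <- list(idx = idx, Wk = Wk)
  }
  if (rcond(M) < rcond_tol)
    stop(paste("singular information: the treatment effect is inestimable",
               "under this allocation (no usable contrast)"), call. = FALSE)
  d <- solve(M, c(rep(0, p - 1L), 1))
  a <- numeric(n)
  for (w in W) a[w$idx] <- w$Wk %*% d
  list(a = a, vtilde = d[p])
}

# scaled quadratic form c * sum_k a_k' Gamma a_k + sum a^2/pi over support
vtilde_of <- function(cells, a, pi, Gamma, c_ratio) {
  quad <- 0
  for (idx in split(seq_len(nrow(cells)), cells$k)) {
    tt <- cells$t[idx]
    quad <- quad + drop(crossprod(a[idx], Gamma[tt, tt, drop = FALSE] %*% a[idx]))
  }
  c_ratio * quad + sum(a^2 / pi)
}

#' BLUE coefficients of the treatment effect for a given allocation
#'
#' Computes the weights `a[k, t]` of the best linear unbiased estimator
#' (equivalently, generalized least squares) of the treatment effect from
#' the cell means, for a fixed allocation of observations. The weights sum
#' to zero within every occupied epoch (eliminating the time effects) and
#' the treated weights sum to 1; empty and prohibited cells have weight 0.
#'
#' @param layout a [trial_layout()].
#' @param pi allocation (K x T matrix, or vector over cells); its support is
#'   the set of occupied cells.
#' @param cac a [cac_model()].
#' @param scale a [design_scale()].
#' @return An object of class `blue_coef`: list with `a` (K x T matrix of
#'   weights, 0 on unoccupied cells, `NA` outside the layout), `variance`
#'   (the [variance_of()] decomposition at this allocation) and `vtilde`
#'   (the scale-free variance `c*sum a'Gamma a + sum a^2/pi`).
#' @export
blue_coefficients <- function(layout, pi, cac, scale) {
  stopifnot(inherits(layout, "trial_layout"), inherits(scale, "design_scale"))
  pim <- validate_allocation(layout, pi)
  Gamma <- gamma_matrix(cac, layout$T)
  v <- pi_vec(layout, pim)
  supp <- which(v > 0)
  if (!length(supp)) stop("allocation support is empty", call. = FALSE)
  cells <- layout$cells[supp, , drop = FALSE]
  g <- gls_engine(cells, v[supp], Gamma, scale$ratio)
  av <- numeric(length(v)); av[supp] <- g$a
  am <- pi_mat(layout, av)
  structure(list(a = am, vtilde = g$vtilde,
                 variance = variance_of(am, pim, layout, cac, scale)),
            class = "blue_coef")
}

#' @export
print.blue_coef <- function(x, ...) {
  cat("BLUE coefficients (cell-mean weights):\n")
  print(round(x$a, 4))
  cat(sprintf("var(theta_hat) = %.6g sigma^2\n", x$variance$variance))
  invisible(x)
}

#' Variance of a linear cell-mean estimator of the treatment effect
#'
#' Evaluates
#' `var = sigma2 * [ rho * sum_k a_k' Gamma a_k + (1-rho)/N * sum a^2/pi ]`
#' for coefficients `a` and allocation `pi`. The first summand is the
#' cluster-level (between-period) contribution, the second the residual
#' sampling contribution. `a` must vanish wherever `pi` does.
#'
#' @param a coefficient matrix or vector (see [blue_coefficients()]).
#' @inheritParams blue_coefficients
#' @return List with `variance`, `cluster_term`, `residual_term` (all in
#'   units of `sigma2`).
#' @export
variance_of <- function(a, pi, layout, cac, scale) {
  stopifnot(inherits(layout, "trial_layout"), inherits(scale, "design_scale"))
  pim <- validate_allocation(layout, pi)
  av <- pi_vec(layout, if (is.matrix(a)) a else pi_mat(layout, a))
  pv <- pi_vec(layout, pim)
  if (any(abs(av[pv == 0]) > 1e-12))
    stop("coefficients are nonzero on an empty cell", call. = FALSE)
  Gamma <- gamma_matrix(cac, layout$T)
  quad <- 0
  for (idx in split(seq_len(nrow(layout$cells)), layout$cells$k)) {
    tt <- layout$cells$t[idx]
    quad <- quad + drop(crossprod(av[idx], Gamma[tt, tt, drop = FALSE] %*% av[idx]))
  }
  supp <- pv > 0
  res <- sum(av[supp]^2 / pv[supp])
  list(variance = scale$sigma2 * (scale$rho * quad + (1 - scale$rho) / scale$N * res),
       cluster_term = scale$sigma2 * scale$rho * quad,
       residual_term = scale$sigma2 * (1 - scale$rho) / scale$N * res)
}

#' Design objective for coefficient arrays
#'
#' The objective `Psi(a) = rho * sum_k a_k' Gamma a_k + (1-rho)/N * (sum |a|)^2`
#' (in `sigma2` units) is the variance of the estimator with weights `a`
#' under the allocation that is optimal for those weights,
#' `pi = |a| / sum |a|`. Minimizing `Psi` over the unbiasedness constraint
#' set (zero epoch sums, treated sum 1) is the convex form of the optimal
#' allocation problem.
#'
#' @inheritParams variance_of
#' @param tol feasibility tolerance for the constraint checks.
#' @export
psi_objective <- function(a, layout, cac, scale, tol = 1e-8) {
  stopifnot(inherits(layout, "trial_layout"), inherits(scale, "design_scale"))
  av <- pi_vec(layout, if (is.matrix(a)) a else pi_mat(layout, a))
  cells <- layout$cells
  colsums <- tapply(av, cells$t, sum)
  if (any(abs(colsums) > tol))
    stop("coefficients violate the zero-sum constraint within an epoch", call. = FALSE)
  if (abs(sum(av * cells$Z) - 1) > tol)
    stop("treated coefficients must sum to 1", call. = FALSE)
  Gamma <- gamma_matrix(cac, layout$T)
  quad <- 0
  for (idx in split(seq_len(nrow(cells)), cells$k)) {
    tt <- cells$t[idx]
    quad <- quad + drop(crossprod(av[idx], Gamma[tt, tt, drop = FALSE] %*% av[idx]))
  }
  scale$sigma2 * (scale$rho * quad + (1 - scale$rho) / scale$N * sum(abs(av))^2)
}

#' Efficiency of an allocation
#'
#' The efficiency of an allocation is the ratio of the optimal design's
#' estimator variance to the allocation's variance (at the same layout,
#' correlation model and scale), so it lies in (0, 1]. It depends on `N` and
#' `rho` only through the ratio `N*rho/(1-rho)`.
#'
#' @inheritParams blue_coefficients
#' @param optimum optionally, a precomputed [optimal_allocation()] result
#'   for the same problem (avoids re-optimizing).
#' @export
design_efficiency <- function(pi, layout, cac, scale, optimum = NULL) {
  if (is.null(optimum)) optimum <- optimal_allocation(layout, cac, scale)
  cand <- blue_coefficients(layout, pi, cac, scale)
  optimum$vtilde / cand$vtilde
}

#' Variance under G-fold replication of the basic layout
#'
#' When G clusters are assigned to each row of the layout (G complete
#' replicates, G*N observations in total), the variance of the treatment
#' effect estimator is reduced by the factor 1/G; relative comparisons
#' between allocations are unchanged.
#'
#' @param variance variance for the basic (single-replicate) layout.
#' @param G number of replicates.
#' @export
replicate_variance <- function(variance, G) {
  if (G < 1) stop("G must be >= 1", call. = FALSE)
  variance / G
}

#' 95% confidence-interval half-width implied by a design variance
#'
#' @param variance estimator variance in `sigma2` units.
#' @export
ci_halfwidth <- function(variance) 1.96 * sqrt(variance)
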