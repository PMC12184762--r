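# Staircase designs for stepped-wedge layouts: support confined to the
# cells immediately before and after each treatment switch, excluding
# baseline and endline: S = {(t-1,t), (t,t); t = 2..K}.

staircase_support_matrix <- function(K) {
  m <- matrix(FALSE, K, K + 1)
  for (t in 2:K) { m[t - 1, t] <- TRUE; m[t, t] <- TRUE }
  m
}

# phi = acosh(1/(alpha*r))/2; the alpha*r -> 1 limit of the cosh profile is
# proportional to k*(K-k)
staircase_phi <- function(ar) {
  if (ar <= 0 || ar > 1) stop("alpha*r must lie in (0, 1]", call. = FALSE)
  if (ar == 1) 0 else acosh(1 / ar) / 2
}

staircase_q <- function(K, ar) {
  k <- seq_len(K - 1)
  q <- if (ar == 1) k * (K - k)
       else { ph <- staircase_phi(ar); cosh(K * ph) - cosh((2 * k - K) * ph) }
  q / sum(q)
}

#' Closed-form optimal staircase allocation
#'
#' The best allocation with staircase support on a K-sequence stepped-wedge
#' layout places proportion `q[k]/2` on each of the two cells flanking the
#' k-th treatment switch, where `q[k]` is proportional to
#' `cosh(K*phi) - cosh((2k-K)*phi)` with `phi = acosh(1/(alpha*r))/2` when
#' `alpha*r < 1`, and to `k*(K-k)` in the limit `alpha*r = 1`. The profile
#' depends on the correlation model only through the first-order cluster
#' autocorrelation `alpha*r`.
#'
#' @param K number of cluster-sequences (>= 2).
#' @param alpha,r parameters of the correlation family; `alpha*r` must lie
#'   in (0, 1\]. (For `alpha*r = 0` the cluster-periods are uncorrelated and
#'   the best natural allocation is [identity_na()], not a staircase.)
#' @return Object of class `staircase_solution`: list with `K`, `ar`, `phi`,
#'   `q` (normalized switch weights, k = 1..K-1) and `allocation`
#'   (K x (K+1) matrix supported on the staircase cells).
#' @examples
#' staircase_allocation(6, 1, 1)$q * 35   # 5 8 9 8 5, i.e. k*(K-k)
#' @export
staircase_allocation <- function(K, alpha, r) {
  if (K < 2 || K != round(K)) stop("K must be an integer >= 2", call. = FALSE)
  cm <- cac_model(alpha, r)
  ar <- alpha * r
  q <- staircase_q(K, ar)
  pi <- matrix(0, K, K + 1)
  for (k in seq_len(K - 1)) {
    pi[k, k + 1] <- q[k] / 2
    pi[k + 1, k + 1] <- q[k] / 2
  }
  structure(list(K = K, ar = ar, phi = staircase_phi(ar), q = q,
                 allocation = pi, cac = cm),
            class = "staircase_solution")
}

#' @export
print.staircase_solution <- function(x, ...) {
  cat(sprintf("Staircase allocation, K = %d, alpha*r = %g\n", x$K, x$ar))
  cat("switch weights q:", paste(sprintf("%.4f", x$q), collapse = " "), "\n")
  invisible(x)
}

#' Variance of the treatment-effect estimator under the optimal staircase
#'
#' Closed form:
#' `sigma2 * [ 2*(1-ar)*rho / (K - coth(phi)*tanh(K*phi)) + 4*(1-rho)/N ]`
#' for `ar = alpha*r < 1`, and
#' `sigma2 * [ 12*rho/(K*(K^2-1)) + 4*(1-rho)/N ]` at `ar = 1`
#' (also the `ar -> 1` limit of the first form).
#'
#' @inheritParams staircase_allocation
#' @param N total observations; `rho` ICC; `sigma2` total variance.
#' @export
staircase_variance <- function(K, alpha, r, N, rho, sigma2 = 1) {
  cac_model(alpha, r)
  ar <- alpha * r
  if (ar <= 0 || ar > 1) stop("alpha*r must lie in (0, 1]", call. = FALSE)
  cl <- if (ar == 1) 12 * rho / (K * (K^2 - 1))
        else {
          ph <- staircase_phi(ar)
          2 * (1 - ar) * rho / (K - cosh(ph) / sinh(ph) * tanh(K * ph))
        }
  sigma2 * (cl + 4 * (1 - rho) / N)
}

# Exact optimality check of the staircase point in the best-natural
# quadratic program, via dual feasibility. Within the staircase support the
# optimum is the closed-form q profile; the multipliers (nu for the total-
# mass constraint, lam_t per epoch balance) are recovered from the support
# cells and the reduced gradients of all other cells in usable epochs must
# be nonnegative. Works cluster-wise without forming the dense quadratic
# form, so it is cheap for any K.
staircase_dual_check <- function(K, alpha, r, tol = 1e-9) {
  ar <- alpha * r
  Gamma <- gamma_matrix(cac_model(alpha, r), K + 1)
  q <- staircase_q(K, ar)
  qq <- c(0, q, 0)                       # q[k] indexed k = 0..K
  ks <- seq_len(K)
  # (Qb)[k,t] = s[k,t] * ( -Gamma[t,k]*q[k-1] + Gamma[t,k+1]*q[k] ): cluster
  # k's staircase cells sit at epochs k (control, -q[k-1]) and k+1
  # (treated, +q[k])
  Qb_col <- function(t) {
    s <- ifelse(t > ks, 1, -1)
    s * (-Gamma[t, ks] * qq[ks] + Gamma[t, ks + 1] * qq[ks + 1])
  }
  cols <- lapply(2:K, Qb_col)
  nu_t <- vapply(seq_along(cols), function(i) cols[[i]][i] + cols[[i]][i + 1],
                 numeric(1))           # (g_treated + g_control), support cells
  lam_t <- vapply(seq_along(cols), function(i) cols[[i]][i] - cols[[i]][i + 1],
                  numeric(1))
  nu <- mean(nu_t)
  if (max(abs(nu_t - nu)) > 1e-7 * max(1, abs(nu)))
    stop("staircase stationarity multipliers are inconsistent", call. = FALSE)
  for (i in seq_along(cols)) {
    t <- i + 1
    s <- ifelse(t > ks, 1, -1)
    g <- 2 * cols[[i]] - lam_t[i] * s - nu
    g[c(t - 1, t)] <- 0                # support cells: stationary by construction
    if (min(g) < -tol * max(1, abs(nu))) return(FALSE)
  }
  TRUE
}

# printed family-specific conditions for staircase best-naturality;
# both amount to a lower bound on the first-order autocorrelation
staircase_condition_analytic <- function(K, alpha, r) {
  ar <- alpha * r
  if (ar >= 1) return(TRUE)
  ph <- staircase_phi(ar)
  tol <- 1e-9            # boundary cases are exact up to floating point
  if (r == 1) {          # BEX
    if (K %% 2 == 1) cosh(K * ph) / cosh(ph) <= 3 * (1 + tol)
    else cosh(K * ph) <= (2 + 1 / alpha) * (1 + tol)
  } else if (alpha == 1) { # DTD
    lhs <- if (K %% 2 == 1) cosh(K * ph) / cosh(ph) else cosh(K * ph)
    lhs <= (1 + r) / (1 - r) * (1 + tol)
  } else {
    NA                   # no closed form outside the named families
  }
}

#' Is the best natural allocation a staircase?
#'
#' Tests whether the staircase solution is the best natural allocation of
#' the K-sequence stepped-wedge layout under the correlation model
#' `(alpha, r)`. This holds whenever the first-order autocorrelation
#' `alpha*r` is close enough to 1; under the exchangeable model it holds for
#' every K.
#'
#' The primary method verifies exact optimality of the closed-form staircase
#' point within the natural cone by dual feasibility of the quadratic
#' program (cheap for any K). For the BEX and DTD families the printed
#' closed-form conditions (`cosh(K*phi)/cosh(phi) <= 3` for odd K and
#' `cosh(K*phi) <= 2 + 1/alpha` for even K under BEX;
#' `cosh(K*phi) <= (1+r)/(1-r)` under DTD) are available as a cross-check,
#' and `method = "both"` raises on disagreement.
#'
#' @inheritParams staircase_allocation
#' @param method `"numerical"` (dual check, default), `"analytic"` (BEX/DTD
#'   closed forms only), or `"both"`.
#' @export
staircase_is_best_na <- function(K, alpha, r, method = c("numerical", "analytic", "both")) {
  method <- match.arg(method)
  cac_model(alpha, r)
  if (alpha * r == 0) return(FALSE)
  if (K < 2 || K != round(K)) stop("K must be an integer >= 2", call. = FALSE)
  num <- if (method != "analytic") staircase_dual_check(K, alpha, r) else NULL
  ana <- if (method != "numerical") staircase_condition_analytic(K, alpha, r) else NULL
  if (method == "numerical") return(num)
  if (method == "analytic") {
    if (is.na(ana))
      stop("no closed-form condition outside the BEX/DTD/EXC families; use the numerical method",
           call. = FALSE)
    return(ana)
  }
  if (!is.na(ana) && num != ana)
    stop(sprintf("numerical (%s) and analytic (%s) staircase conditions disagree at K=%d, alpha=%g, r=%g",
                 num, ana, K, alpha, r), call. = FALSE)
  num
}

#' Largest K for which the best natural allocation is a staircase
#'
#' @inheritParams staircase_allocation
#' @param K_max scan cap (the exchangeable model returns `Inf` directly).
#' @export
max_k_staircase <- function(alpha, r, K_max = 200) {
  cac_model(alpha, r)
  if (alpha * r == 0) return(0L)
  if (alpha == 1 && r == 1) return(Inf)
  best <- 0L
  for (K in 2:K_max) if (staircase_dual_check(K, alpha, r)) best <- K
  best
}

#' Critical autocorrelation for staircase best-naturality
#'
#' For the BEX family (bisection on `alpha` at `r = 1`) or the DTD family
#' (bisection on `r` at `alpha = 1`), returns the parameter threshold above
#' which the best natural allocation of a K-sequence stepped-wedge layout
#' has staircase support, using the exact dual-feasibility check.
#'
#' @param K number of cluster-sequences.
#' @param family `"bex"` or `"dtd"`.
#' @param iters bisection iterations.
#' @export
cac_threshold <- function(K, family = c("bex", "dtd"), iters = 50) {
  family <- match.arg(family)
  ok <- function(p) if (family == "bex") staircase_dual_check(K, p, 1)
                    else staircase_dual_check(K, 1, p)
  lo <- 1e-4; hi <- 1
  if (ok(lo)) return(lo)
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    if (ok(mid)) hi <- mid else lo <- mid
  }
  hi
}

#' ICV threshold and cluster-size bound for staircase optimality
#'
#' When the staircase is the best natural allocation, it is the overall
#' optimal allocation exactly when the index of cluster variation satisfies
#' `S <= S1`. Writing `m = S1/(1-S1)`, the staircase is optimal at
#' intra-cluster correlation `rho` when the average cluster size satisfies
#' `M <= m*(1-rho)/rho`; the largest such integer is reported (the bound
#' rounded to the nearest integer, matching how the limits are tabulated).
#' Under the exchangeable model `S1 = (K+1)/(K+4)` in closed form.
#'
#' @inheritParams staircase_allocation
#' @param rho optionally, ICC value(s) at which to evaluate the maximum
#'   average cluster size.
#' @return List with `S1`, `m`, and (when `rho` given) `max_M`.
#' @export
staircase_s1 <- function(K, alpha, r, rho = NULL) {
  if (!staircase_is_best_na(K, alpha, r))
    stop("the staircase is not the best natural allocation here; use s1_threshold on the layout",
         call. = FALSE)
  lay <- sw_layout(K)
  sc <- staircase_allocation(K, alpha, r)
  S1 <- s1_exact(lay, gamma_matrix(cac_model(alpha, r), K + 1), sc$allocation)
  m <- S1 / (1 - S1)
  out <- list(S1 = S1, m = m)
  if (!is.null(rho)) out$max_M <- round(m * (1 - rho) / rho)
  out
}

#' Optimal allocation under the exchangeable model at any scale
#'
#' Under the exchangeable (EXC) correlation model the staircase is the best
#' natural allocation for every K, and is the overall optimum exactly when
#' `S <= S1 = (K+1)/(K+4)`. Above the threshold the optimum is a weighted
#' combination of the staircase with a second component whose support
#' includes the corner cells (1,1) and (K, K+1); the staircase weight is
#' `w = (K+1)*(1-S)/(3*S)` (equal to 1 at the threshold). For `S > S1` the
#' optimum is computed numerically and, because the EXC model's correlation
#' matrix is singular, the skew-symmetrized average of the solution is
#' returned (same variance, canonical representative).
#'
#' @param K number of cluster-sequences.
#' @param S index of cluster variation, in (0, 1).
#' @return List with `allocation`, `staircase_weight` (`w`, capped at 1),
#'   `S1`, and `variance_vtilde` is omitted; use [variance_of()] at a
#'   concrete scale for variances.
#' @export
exc_optimum <- function(K, S) {
  if (S <= 0 || S >= 1) stop("S must lie in (0, 1)", call. = FALSE)
  S1 <- (K + 1) / (K + 4)
  w <- min(1, (K + 1) * (1 - S) / (3 * S))
  if (S <= S1) {
    alloc <- staircase_allocation(K, 1, 1)$allocation
  } else {
    lay <- sw_layout(K)
    sc <- design_scale(K = K, S = S)
    fit <- optimal_allocation(lay, cac_exc(), sc)
    alloc <- (fit$allocation + skew_transform(fit$allocation)) / 2
  }
  list(allocation = alloc, staircase_weight = w, S1 = S1)
}

#' Tabulate staircase properties over parameter grids
#'
#' `table_staircase_max_k` reproduces, for a grid of `(alpha, r)`, the
#' largest number of cluster-sequences for which the best natural allocation
#' has staircase support. `table_cac_thresholds` gives, per K, the DTD
#' r-threshold (with the implied study-length autocorrelation `r^K`) and the
#' BEX alpha-threshold. `table_max_cluster_size` gives, per (rho, K), the
#' largest average cluster size for which the optimal design is a staircase
#' under a DTD model with fixed study-length autocorrelation.
#'
#' @param alphas,rs,Ks,rhos parameter grids.
#' @param rK study-length cluster autocorrelation `r^K` held fixed.
#' @return A data frame.
#' @export
table_staircase_max_k <- function(alphas = c(0.5, 0.6, 0.7, 0.8, 0.9, 0.95, 0.99, 1),
                                  rs = c(0.5, 0.6, 0.7, 0.8, 0.9, 0.95, 0.99, 1)) {
  out <- expand.grid(alpha = alphas, r = rs)
  out$max_K <- mapply(function(a, r) max_k_staircase(a, r), out$alpha, out$r)
  out
}

#' @rdname table_staircase_max_k
#' @export
table_cac_thresholds <- function(Ks = c(3, 4, 6, 8, 10, 15, 20, 30, 50, 100)) {
  r_thr <- vapply(Ks, function(K) cac_threshold(K, "dtd"), numeric(1))
  a_thr <- vapply(Ks, function(K) cac_threshold(K, "bex"), numeric(1))
  data.frame(K = Ks, dtd_r_threshold = r_thr, dtd_rK_threshold = r_thr^Ks,
             bex_alpha_threshold = a_thr)
}

#' @rdname table_staircase_max_k
#' @export
table_max_cluster_size <- function(Ks = c(6, 10, 20, 30, 50),
                                   rhos = c(0.01, 0.05, 0.10, 0.25),
                                   rK = 0.66) {
  out <- expand.grid(rho = rhos, K = Ks)
  ms <- vapply(Ks, function(K) staircase_s1(K, 1, rK^(1 / K))$m, numeric(1))
  out$max_M <- round(ms[match(out$K, Ks)] * (1 - out$rho) / out$rho)
  out
}
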