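# Natural allocations: designs whose BLUE is the simple difference between
# the means of the treated and control observations, i.e. whose GLS weights
# are a[k,t] = 2*(2*Z[k,t]-1)*pi[k,t]. Whether an allocation is natural
# depends only on the cluster-autocorrelation matrix, never on N or rho.

natural_coef <- function(layout, pim) 2 * (2 * layout$Z - 1) * pim

#' Check whether an allocation is natural
#'
#' An allocation is natural when the BLUE of the treatment effect equals the
#' naive treated-minus-control difference of cell means, i.e. the GLS
#' weights are `2*(2Z-1)*pi`. Naturality requires treated/control balance of
#' the proportions within every epoch, and the verdict is independent of the
#' sample-size scale; it is verified here by computing the BLUE at several
#' probe scales and comparing against the natural weights in sup-norm.
#'
#' @param pi allocation matrix (or cell vector).
#' @param layout a [trial_layout()].
#' @param cac a [cac_model()].
#' @param probe_scales ICV values at which the BLUE is recomputed.
#' @param tol relative sup-norm tolerance on the coefficient gap.
#' @return List with `is_natural`, `max_deviation` (relative sup-norm over
#'   all probes), `na_coefficients` (the matrix `2(2Z-1)pi`) and
#'   `per_epoch_balance` (treated minus control proportion per epoch).
#' @export
check_natural <- function(pi, layout, cac, probe_scales = c(0.01, 0.5, 0.99),
                          tol = 1e-6) {
  stopifnot(inherits(layout, "trial_layout"))
  pim <- validate_allocation(layout, pi)
  anat <- natural_coef(layout, pim)
  ref <- max(abs(anat), na.rm = TRUE)
  dev <- 0
  for (S in probe_scales) {
    sc <- design_scale(K = layout$K, S = S)
    b <- blue_coefficients(layout, pim, cac, sc)
    dev <- max(dev, max(abs(b$a - anat), na.rm = TRUE) / ref)
  }
  bal <- sapply(seq_len(layout$T), function(t) {
    z <- layout$Z[, t]; p <- pim[, t]
    sum(p[!is.na(z) & z == 1]) - sum(p[!is.na(z) & z == 0])
  })
  list(is_natural = dev < tol, max_deviation = dev,
       na_coefficients = anat, per_epoch_balance = bal)
}

# Primal active-set solver for the best-natural quadratic program:
#   minimize  sum_k b_k' (s s' o Gamma) b_k   (s = 2Z - 1, pi = b/2)
#   s.t.      sum_k s[k,t] b[k,t] = 0 for every usable epoch t,
#             sum(b) = 2,  b >= 0.
# Cells in epochs lacking both arms cannot carry natural mass and are
# dropped up front. The KKT systems are solved directly; MASS::ginv is the
# fallback for the positive-semidefinite EXC case, where the minimizer of
# the quadratic form need not be unique.
best_natural_qp <- function(layout, Gamma, maxit = NULL) {
  cells <- layout$cells
  s_all <- 2 * cells$Z - 1
  usable <- vapply(split(cells$Z, cells$t), function(z) any(z == 1) && any(z == 0),
                   logical(1))
  keep <- usable[as.character(cells$t)]
  idx0 <- which(keep)
  cc <- cells[idx0, , drop = FALSE]
  sv <- s_all[idx0]
  n <- nrow(cc)
  if (is.null(maxit)) maxit <- 10L * n + 50L
  Q <- matrix(0, n, n)
  for (ii in split(seq_len(n), cc$k)) {
    tt <- cc$t[ii]
    Q[ii, ii] <- outer(sv[ii], sv[ii]) * Gamma[tt, tt, drop = FALSE]
  }
  eps <- sort(unique(cc$t))
  E <- matrix(0, length(eps) + 1L, n)
  for (j in seq_along(eps)) E[j, cc$t == eps[j]] <- sv[cc$t == eps[j]]
  E[length(eps) + 1L, ] <- 1
  f <- c(rep(0, length(eps)), 2)
  # feasible start: equal split of each epoch's mass between the two arms
  b <- numeric(n)
  for (j in seq_along(eps)) {
    ii <- which(cc$t == eps[j])
    tr <- ii[cc$Z[ii] == 1]; ct <- ii[cc$Z[ii] == 0]
    w <- 2 / length(eps)
    b[tr] <- w / 2 / length(tr); b[ct] <- w / 2 / length(ct)
  }
  act <- rep(FALSE, n)
  solve_eq <- function(free) {
    nf <- sum(free)
    KKT <- rbind(cbind(2 * Q[free, free, drop = FALSE], t(E[, free, drop = FALSE])),
                 cbind(E[, free, drop = FALSE], matrix(0, nrow(E), nrow(E))))
    rhs <- c(rep(0, nf), f)
    sol <- tryCatch(solve(KKT, rhs),
                    error = function(e) drop(MASS::ginv(KKT) %*% rhs))
    list(b = sol[seq_len(nf)], lam = sol[(nf + 1):length(sol)])
  }
  for (iter in seq_len(maxit)) {
    free <- !act
    sol <- solve_eq(free)
    bstar <- numeric(n); bstar[free] <- sol$b
    if (min(bstar[free]) >= -1e-11) {
      b <- pmax(bstar, 0)
      g <- drop(2 * Q %*% b - crossprod(E, sol$lam))
      if (!any(act)) break
      viol <- which(act)[g[act] < -1e-9]
      if (!length(viol)) break
      act[viol[which.min(g[viol])]] <- FALSE
    } else {
      d <- bstar - b
      blk <- which(free & d < -1e-14)
      step <- -b[blk] / d[blk]
      j <- blk[which.min(step)]
      alpha <- max(0, min(1, step[which.min(step)]))
      b <- pmax(b + alpha * d, 0); b[j] <- 0
      act[j] <- TRUE
    }
  }
  piv <- numeric(nrow(cells)); piv[idx0] <- b / 2
  piv / sum(piv)
}

#' Best natural allocation of a layout
#'
#' The minimum-variance natural allocation. By the optimality threshold
#' result it is the overall optimal allocation whenever the index of cluster
#' variation does not exceed the threshold [s1_threshold()], and for any
#' scale its estimator is the plain difference between treated and control
#' means.
#'
#' Two independent routes are implemented and, when `check = TRUE`, required
#' to agree: (A, primary) a convex quadratic program over the natural cone
#' (per-epoch treated/control balance, total mass fixed, nonnegativity)
#' solved by an active-set method; (B) the alternating optimizer run at
#' `S = 1/(K+1)`, a scale at which the optimum is guaranteed to be the best
#' natural allocation. Route A is also verified to be natural via
#' [check_natural()].
#'
#' @inheritParams check_natural
#' @param method `"qp"` (default), `"optimize"`, or `"both"` (compare).
#' @param check verify naturality of the result and, for `"both"`,
#'   agreement of the two routes to `1e-6` relative variance.
#' @return A K x T allocation matrix.
#' @export
best_natural <- function(layout, cac, method = c("qp", "optimize", "both"),
                         check = TRUE) {
  method <- match.arg(method)
  stopifnot(inherits(layout, "trial_layout"))
  Gamma <- gamma_matrix(cac, layout$T)
  piv_b <- NULL
  if (method %in% c("optimize", "both")) {
    sc <- design_scale(K = layout$K, S = 1 / (layout$K + 1))
    piv_b <- pi_vec(layout, optimal_allocation(layout, cac, sc)$allocation)
  }
  if (method == "optimize") {
    piv <- piv_b
  } else {
    piv <- best_natural_qp(layout, Gamma)
  }
  pim <- pi_mat(layout, piv)
  if (method == "both") {
    v_a <- na_variance_quad(layout, Gamma, piv)
    v_b <- na_variance_quad(layout, Gamma, piv_b)
    if (abs(v_a - v_b) > 1e-6 * max(v_b, 1e-300))
      stop(sprintf(paste("best-natural routes disagree (relative variance gap %.2e):",
                         "an optimality assumption is violated"),
                   abs(v_a - v_b) / v_b), call. = FALSE)
  }
  if (check) {
    chk <- check_natural(pim, layout, cac)
    if (!chk$is_natural)
      stop(sprintf(paste("best-natural candidate failed the naturality check",
                         "(max coefficient deviation %.2e)"), chk$max_deviation),
           call. = FALSE)
  }
  pim
}

# cluster quadratic form of the natural coefficients: sum_k a_k' Gamma a_k
# with a = 2(2Z-1)pi; the scale-free part of the natural-variance formula
na_variance_quad <- function(layout, Gamma, piv) {
  cells <- layout$cells
  av <- 2 * (2 * cells$Z - 1) * piv
  quad <- 0
  for (ii in split(seq_len(nrow(cells)), cells$k)) {
    tt <- cells$t[ii]
    quad <- quad + drop(crossprod(av[ii], Gamma[tt, tt, drop = FALSE] %*% av[ii]))
  }
  quad
}

#' Variance of the estimator under a natural allocation
#'
#' For a natural allocation the variance reduces to
#' `sigma2 * [ rho * sum_k a_k' Gamma a_k + 4*(1-rho)/N ]` with
#' `a = 2(2Z-1)pi`: every observation carries the same weight, so the
#' residual term is simply `4(1-rho)/N`.
#'
#' @inheritParams check_natural
#' @param scale a [design_scale()].
#' @export
natural_variance <- function(pi, layout, cac, scale) {
  pim <- validate_allocation(layout, pi)
  Gamma <- gamma_matrix(cac, layout$T)
  quad <- na_variance_quad(layout, Gamma, pi_vec(layout, pim))
  scale$sigma2 * (scale$rho * quad + 4 * (1 - scale$rho) / scale$N)
}

# Exact ICV threshold from the subgradient (KKT) conditions of the design
# objective at the natural coefficients a = 2(2Z-1)pi0 (sum|a| = 2).
# With multipliers lam_t (epoch constraints) and mu (treated-sum):
#   support cell:  c*h[k,t] + 4*sgn(a[k,t]) = lam_t + mu*Z[k,t]
#   zero cell:     |c*h[k,t] - lam_t - mu*Z[k,t]| <= 4
# where h[k,t] = 2*(A Gamma)[k,t] and c = N*rho/(1-rho). Every condition is
# affine in c, so feasibility holds on an interval [0, c*]; c* is located by
# bisection on feasibility to machine precision and S1 = c*/(K + c*).
s1_exact <- function(layout, Gamma, pi0m, tol_sup = 1e-9) {
  K <- layout$K; T <- layout$T
  Zm <- layout$Z
  A <- 2 * (2 * Zm - 1) * pi0m
  A[is.na(A)] <- 0
  H <- 2 * A %*% Gamma
  supp <- !is.na(pi0m) & pi0m > tol_sup
  avail <- !is.na(Zm)
  feasible <- function(cr) {
    G <- cr * H
    lam <- rep(NA_real_, T); mu <- NA_real_
    for (t in seq_len(T)) {
      ks <- which(supp[, t])
      if (!length(ks)) next
      kc <- ks[Zm[ks, t] == 0]; kt <- ks[Zm[ks, t] == 1]
      if (length(kc)) lam[t] <- G[kc[1], t] - 4
      if (length(kt) && length(kc)) {
        mu_t <- G[kt[1], t] + 4 - lam[t]
        if (is.na(mu)) mu <- mu_t
        else if (abs(mu_t - mu) > 1e-6 * max(1, abs(mu))) return(FALSE)
      }
    }
    if (is.na(mu)) return(FALSE)
    for (t in seq_len(T)) {
      ks <- which(supp[, t]); if (!length(ks)) next
      for (k in ks) {
        lhs <- G[k, t] + 4 * (2 * Zm[k, t] - 1)
        if (abs(lhs - (lam[t] + mu * Zm[k, t])) > 1e-6 * max(1, abs(mu)))
          return(FALSE)
      }
      for (k in which(avail[, t] & !supp[, t]))
        if (abs(G[k, t] - lam[t] - mu * Zm[k, t]) > 4 + 1e-9) return(FALSE)
    }
    for (t in which(is.na(lam))) {
      ks <- which(avail[, t]); if (!length(ks)) next
      lo <- max(G[ks, t] - mu * Zm[ks, t] - 4)
      hi <- min(G[ks, t] - mu * Zm[ks, t] + 4)
      if (lo > hi + 1e-9) return(FALSE)
    }
    TRUE
  }
  if (!feasible(1e-9))
    stop("natural allocation fails its own optimality conditions at S ~ 0",
         call. = FALSE)
  hi_cap <- 1e12
  if (feasible(hi_cap)) return(1)  # optimal for every scale
  lo <- 0; hi <- hi_cap
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (feasible(mid)) lo <- mid else hi <- mid
  }
  lo / (layout$K + lo)
}

#' ICV threshold of exact optimality of the best natural allocation
#'
#' For every layout and correlation model there is a threshold value `S1 >=
#' 1/(K+1)` of the index of cluster variation such that the best natural
#' allocation is the overall optimal allocation exactly when `S <= S1`.
#'
#' Two methods are provided. `"exact"` (default) computes the threshold from
#' the subgradient optimality conditions of the design objective at the
#' natural coefficients: all conditions are affine in the ratio
#' `N*rho/(1-rho)`, so the supremum is located to machine precision without
#' repeated optimization. `"bisect"` estimates the threshold operationally
#' as the largest S at which the efficiency of the best natural allocation
#' is at least `1 - eff_tol`, by bisection over repeated runs of the
#' alternating optimizer; with the default `eff_tol = 1e-4` this reproduces
#' a "99.99% efficient" reading of the threshold and slightly overshoots the
#' exact value, because the efficiency dip above `S1` opens quadratically.
#'
#' @inheritParams best_natural
#' @param method `"exact"` or `"bisect"`.
#' @param eff_tol efficiency slack defining the bisection threshold.
#' @param bisect_iter bisection iterations (method `"bisect"`).
#' @param pi0 optionally a precomputed best natural allocation.
#' @return List with `S1`, `S90` (the 90%-efficiency threshold, only
#'   computed when `with_s90 = TRUE`), `best_na` (the allocation) and
#'   `method`.
#' @param with_s90 also compute the 90%-efficiency threshold (requires
#'   optimization runs).
#' @export
s1_threshold <- function(layout, cac, method = c("exact", "bisect"),
                         eff_tol = 1e-4, bisect_iter = 40, pi0 = NULL,
                         with_s90 = FALSE) {
  method <- match.arg(method)
  stopifnot(inherits(layout, "trial_layout"))
  Gamma <- gamma_matrix(cac, layout$T)
  if (is.null(pi0)) pi0 <- best_natural(layout, cac)
  S1 <- if (method == "exact") s1_exact(layout, Gamma, pi0)
        else s_eff_threshold(layout, cac, target = 1 - eff_tol,
                             bisect_iter = bisect_iter, pi0 = pi0)
  out <- list(S1 = S1, best_na = pi0, method = method)
  if (with_s90)
    out$S90 <- s_eff_threshold(layout, cac, target = 0.90,
                               bisect_iter = bisect_iter, pi0 = pi0)
  out
}

#' ICV threshold at which the best natural allocation attains a target
#' efficiency
#'
#' The efficiency of the best natural allocation is 1 up to [s1_threshold()]
#' and decreases beyond it; this function locates, by bisection on S with a
#' warm-started optimizer, the largest S at which the efficiency is at least
#' `target` (e.g. 0.90 for the 90%-efficiency threshold).
#'
#' @inheritParams s1_threshold
#' @param target efficiency target in (0, 1).
#' @export
s_eff_threshold <- function(layout, cac, target = 0.90, bisect_iter = 40,
                            pi0 = NULL) {
  stopifnot(inherits(layout, "trial_layout"))
  K <- layout$K
  Gamma <- gamma_matrix(cac, layout$T)
  if (is.null(pi0)) pi0 <- best_natural(layout, cac)
  pi0v <- pi_vec(layout, pi0)
  lo <- 1 / (K + 1); hi <- 1 - 1e-9
  eff_at <- function(S, warm) {
    sc <- design_scale(K = K, S = S)
    init <- if (is.null(warm)) NULL else pi_mat(layout, 0.98 * warm + 0.02 / length(warm))
    opt <- optimal_allocation(layout, cac, sc, init = init, restart = FALSE)
    supp <- pi0v > 0
    cells0 <- layout$cells[supp, , drop = FALSE]
    v0 <- gls_engine(cells0, pi0v[supp], Gamma, sc$ratio)$vtilde
    list(eff = opt$vtilde / v0, pi = pi_vec(layout, opt$allocation))
  }
  e_lo <- eff_at(lo, NULL)
  if (e_lo$eff < target - 1e-9)
    stop(sprintf(paste("efficiency %.6f below target at S = 1/(K+1);",
                       "this contradicts the optimality threshold result"),
                 e_lo$eff), call. = FALSE)
  warm <- e_lo$pi
  for (i in seq_len(bisect_iter)) {
    mid <- (lo + hi) / 2
    e <- eff_at(mid, warm)
    warm <- e$pi
    if (e$eff >= target) lo <- mid else hi <- mid
  }
  lo
}

#' Closed-form best natural allocations for two-sequence layouts
#'
#' Under a discrete-time decay correlation `Gamma[s,t] = r^|s-t|`, the best
#' natural allocation of a K = 2 parallel or cross-over layout is fully
#' optimal for every scale (`S1 = 1`) and has closed form: the four corner
#' cells receive `1 / (2*(2 + (T-2)*(1-u)))` each and every interior cell
#' `(1-u)` times that, with `u = +r` (parallel) or `u = -r` (cross-over).
#'
#' @param T number of epochs.
#' @param r decay parameter of the DTD model.
#' @param kind `"parallel"` or `"crossover"`.
#' @return A 2 x T allocation matrix.
#' @export
parallel_crossover_na <- function(T, r, kind = c("parallel", "crossover")) {
  kind <- match.arg(kind)
  if (r < 0 || r > 1) stop("r must lie in [0, 1]", call. = FALSE)
  u <- if (kind == "parallel") r else -r
  den <- 2 * (2 + (T - 2) * (1 - u))
  pi <- matrix(0, 2, T)
  pi[, 1] <- 1 / den; pi[, T] <- 1 / den
  if (T > 2) pi[, 2:(T - 1)] <- (1 - u) / den
  pi
}

#' Closed-form best natural allocation for uncorrelated cluster-periods
#'
#' When the cluster-autocorrelation matrix is the identity (alpha or r equal
#' to 0), the best natural allocation of a stepped-wedge layout weights the
#' cell in column t (t = 2..K) proportionally to `K-t+1` above the treatment
#' boundary (`k < t`) and `t-1` on/below it, with empty baseline and endline
#' columns; it is fully optimal for every scale and the estimator variance
#' is `sigma2 * (6*rho/(K^2-1) + 4*(1-rho)/N)`.
#'
#' @param K number of cluster-sequences.
#' @return List with `allocation` (K x (K+1) matrix) and `variance`, a
#'   function of `(N, rho, sigma2)`.
#' @export
identity_na <- function(K) {
  if (K < 2) stop("K must be >= 2", call. = FALSE)
  w <- matrix(0, K, K + 1)
  for (t in 2:K) for (k in seq_len(K)) w[k, t] <- if (k < t) K - t + 1 else t - 1
  w <- w / sum(w)
  list(allocation = w,
       variance = function(N, rho, sigma2 = 1)
         sigma2 * (6 * rho / (K^2 - 1) + 4 * (1 - rho) / N))
}
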