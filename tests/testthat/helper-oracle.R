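# Independent oracle: minimize the design objective Psi over the
# unbiasedness constraint set. Splitting a = p - q with p, q >= 0 turns the
# non-smooth (sum |a|)^2 term into the smooth quadratic (sum (p+q))^2 (any
# overlap p_i q_i > 0 strictly increases it), so Psi minimization is an
# ordinary convex QP with equality constraints and nonnegativity, solved
# here by a generic primal active-set method. Deliberately shares no code
# path with the alternating optimizer.
psi_oracle_min <- function(layout, cac, scale) {
  cells <- layout$cells
  n <- nrow(cells)
  eps <- sort(unique(cells$t))
  C <- matrix(0, length(eps) + 1, n)
  for (j in seq_along(eps)) C[j, cells$t == eps[j]] <- 1
  C[length(eps) + 1, ] <- cells$Z
  d <- c(rep(0, length(eps)), 1)
  Gamma <- gamma_matrix(cac, layout$T)
  G <- matrix(0, n, n)
  for (ii in split(seq_len(n), cells$k))
    G[ii, ii] <- Gamma[cells$t[ii], cells$t[ii], drop = FALSE]
  w <- (1 - scale$rho) / scale$N
  ones2 <- matrix(1, 2 * n, 2 * n)
  H <- scale$rho * rbind(cbind(G, -G), cbind(-G, G)) + w * ones2
  Aeq <- cbind(C, -C)
  a0 <- drop(MASS::ginv(C) %*% d)
  x0 <- c(pmax(a0, 0), pmax(-a0, 0))   # feasible by construction
  x <- generic_qp_activeset(H, Aeq, d, x0)
  drop(x %*% H %*% x) * scale$sigma2
}

# minimal primal active-set solver for min x'Hx s.t. Aeq x = b, x >= 0,
# from a feasible start (H positive semidefinite; singular KKT systems
# solved in the min-norm sense). Test-side utility only.
generic_qp_activeset <- function(H, Aeq, b, x0, maxit = 500) {
  n <- ncol(H)
  x <- x0
  act <- x <= 0
  for (it in seq_len(maxit)) {
    free <- !act
    nf <- sum(free)
    KKT <- rbind(cbind(2 * H[free, free, drop = FALSE],
                       t(Aeq[, free, drop = FALSE])),
                 cbind(Aeq[, free, drop = FALSE],
                       matrix(0, nrow(Aeq), nrow(Aeq))))
    rhs <- c(rep(0, nf), b)
    sol <- tryCatch(solve(KKT, rhs),
                    error = function(e) drop(MASS::ginv(KKT) %*% rhs))
    xs <- numeric(n); xs[free] <- sol[seq_len(nf)]
    if (min(xs[free]) >= -1e-11) {
      x <- pmax(xs, 0)
      # multipliers from free-variable stationarity (the KKT block from a
      # min-norm solve is unreliable when H is singular)
      grad <- drop(2 * H %*% x)
      lam <- drop(MASS::ginv(t(Aeq[, free, drop = FALSE])) %*% grad[free])
      g <- grad - drop(crossprod(Aeq, lam))
      if (!any(act)) break
      viol <- which(act)[g[act] < -1e-9]
      if (!length(viol)) break
      act[viol[which.min(g[viol])]] <- FALSE
    } else {
      dx <- xs - x
      blk <- which(free & dx < -1e-14)
      step <- -x[blk] / dx[blk]
      j <- blk[which.min(step)]
      alpha <- max(0, min(1, min(step)))
      x <- pmax(x + alpha * dx, 0); x[j] <- 0
      act[j] <- TRUE
    }
  }
  x
}

# random member of the constraint set (for identity/property tests)
random_feasible_a <- function(layout, seed) {
  cells <- layout$cells
  n <- nrow(cells)
  eps <- sort(unique(cells$t))
  C <- matrix(0, length(eps) + 1, n)
  for (j in seq_along(eps)) C[j, cells$t == eps[j]] <- 1
  C[length(eps) + 1, ] <- cells$Z
  d <- c(rep(0, length(eps)), 1)
  a0 <- drop(MASS::ginv(C) %*% d)
  rk <- qr(C)$rank
  NS <- svd(C, nu = 0, nv = n)$v[, (rk + 1):n, drop = FALSE]
  set.seed(seed)
  a0 + drop(NS %*% stats::rnorm(ncol(NS)))
}

staircase_support_of <- function(K) {
  m <- matrix(FALSE, K, K + 1)
  for (t in 2:K) { m[t - 1, t] <- TRUE; m[t, t] <- TRUE }
  m
}

support_of <- function(pi, thr = 1e-5) !is.na(pi) & pi >= thr
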