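#' Optimal allocation of observations by alternating minimization
#'
#' Finds the allocation of a fixed total number of observations over the
#' cells of a layout that minimizes the variance of the GLS (BLUE) estimator
#' of the treatment effect, by alternating two exact partial minimizations:
#'
#' 1. for the current allocation, compute the BLUE coefficients `a` (a GLS
#'    fit on cell means);
#' 2. update the allocation to `pi = |a| / sum(|a|)`, the allocation that
#'    minimizes the variance for those coefficients.
#'
#' Each step cannot increase the variance, so the iteration converges
#' monotonically; with an invertible correlation matrix the limit is the
#' unique optimum. A cell whose proportion reaches zero can never re-enter,
#' so the initial allocation should place mass on every permitted cell (the
#' default, uniform, does). A safeguard restart mixes 1% uniform mass into
#' the converged allocation and re-converges; the better of the two results
#' is returned.
#'
#' @param layout a [trial_layout()].
#' @param cac a [cac_model()].
#' @param scale a [design_scale()]; only the ratio `N*rho/(1-rho)` affects
#'   the optimal allocation.
#' @param init initial allocation (matrix or cell vector); default uniform
#'   over permitted cells.
#' @param prohibit cells unavailable for sampling: a logical K x T matrix,
#'   or a two-column matrix/data frame of (k, t) indices. Their coefficients
#'   are pinned to zero throughout the optimization.
#' @param tol_var convergence tolerance on the relative variance change.
#' @param tol_fix convergence tolerance on the fixed-point residual
#'   `max |pi - |a|/sum|a||`.
#' @param max_iter iteration cap.
#' @param restart logical; perform the safeguard restart (default TRUE).
#' @param drop_tol proportions below this are treated as numerically dead
#'   and removed from the active support (well below any reporting
#'   threshold; this is a floating-point guard, not a design decision).
#' @return An object of class `opt_design`: list with `allocation` (K x T
#'   matrix; prohibited cells 0, absent cells `NA`), `coefficients` (BLUE
#'   weights), `variance` (list from [variance_of()]), `vtilde`, `trace`
#'   (per-iteration variance sequence, in `sigma2` units), `iterations`,
#'   `converged`, `fixres`, `support` (logical matrix, proportions >= 1e-5),
#'   and the inputs.
#' @examples
#' lay <- sw_layout(4)
#' fit <- optimal_allocation(lay, cac_bex(0.7), design_scale(K = 4, ratio = 80/3))
#' fit
#' @export
optimal_allocation <- function(layout, cac, scale, init = NULL, prohibit = NULL,
                               tol_var = 1e-12, tol_fix = 1e-10, max_iter = 1e5,
                               restart = TRUE, drop_tol = 1e-11) {
  stopifnot(inherits(layout, "trial_layout"), inherits(scale, "design_scale"))
  Gamma <- gamma_matrix(cac, layout$T)
  cells <- layout$cells
  n <- nrow(cells)
  permitted <- rep(TRUE, n)
  if (!is.null(prohibit)) {
    if (is.logical(prohibit) && is.matrix(prohibit)) {
      permitted <- !prohibit[cbind(cells$k, cells$t)]
    } else {
      pr <- as.matrix(prohibit)
      key <- paste(cells$k, cells$t)
      permitted <- !(key %in% paste(pr[, 1], pr[, 2]))
    }
    sub <- cells[permitted, , drop = FALSE]
    ok <- any(sapply(split(sub$Z, sub$t), function(z) any(z == 1) && any(z == 0)))
    if (!ok)
      stop("prohibiting these cells destroys the treatment contrast", call. = FALSE)
  }
  if (is.null(init)) {
    piv <- ifelse(permitted, 1 / sum(permitted), 0)
  } else {
    piv <- pi_vec(layout, validate_allocation(layout, init))
    piv[!permitted] <- 0
    piv <- piv / sum(piv)
    if (any(permitted & piv == 0))
      warning("initial allocation has empty permitted cells; they can never re-enter")
  }

  run <- function(piv) {
    trace <- numeric(0)
    vprev <- Inf
    fixres <- Inf; relch <- Inf
    g <- NULL
    for (it in seq_len(max_iter)) {
      act <- which(piv > 0)
      # during the iteration a looser conditioning guard is used: epochs on
      # their way to emptiness pass through near-singular states just before
      # their cells fall under drop_tol
      g <- gls_engine(cells[act, , drop = FALSE], piv[act], Gamma, scale$ratio,
                      rcond_tol = 1e-13)
      v <- g$vtilde
      trace <- c(trace, v)
      av <- numeric(n); av[act] <- g$a
      newpi <- abs(av) / sum(abs(av))
      newpi[newpi < drop_tol] <- 0
      newpi <- newpi / sum(newpi)
      fixres <- max(abs(piv - newpi))
      relch <- abs(vprev - v) / v
      piv <- newpi; vprev <- v
      if (relch < tol_var && fixres < tol_fix) break
    }
    list(pi = piv, a = av, vtilde = v, trace = trace, iterations = it,
         fixres = fixres, converged = relch < tol_var && fixres < tol_fix)
  }

  res <- run(piv)
  if (restart) {
    mix <- 0.99 * res$pi + 0.01 * ifelse(permitted, 1 / sum(permitted), 0)
    res2 <- run(mix / sum(mix))
    if (res2$vtilde < res$vtilde * (1 - 1e-9)) res <- res2
  }
  res$a[res$pi == 0] <- 0   # cells dropped in the final update carry no weight

  am <- pi_mat(layout, res$a)
  pim <- pi_mat(layout, res$pi)
  vfac <- scale$sigma2 * (1 - scale$rho) / scale$N
  structure(list(
    allocation = pim,
    coefficients = am,
    vtilde = res$vtilde,
    variance = variance_of(am, pim, layout, cac, scale),
    trace = vfac * res$trace,
    iterations = res$iterations,
    converged = res$converged,
    fixres = res$fixres,
    support = !is.na(pim) & pim >= 1e-5,
    layout = layout, cac = cac, scale = scale,
    prohibited = !permitted
  ), class = "opt_design")
}

#' Optimize over a sub-layout with prohibited cells
#'
#' Convenience wrapper around [optimal_allocation()] with the `prohibit`
#' argument; the coefficients of prohibited cells are held at zero
#' throughout the minimization.
#'
#' @inheritParams optimal_allocation
#' @param prohibited_cells cells to exclude (see `prohibit` in
#'   [optimal_allocation()]).
#' @export
optimize_sublayout <- function(layout, prohibited_cells, cac, scale, ...) {
  optimal_allocation(layout, cac, scale, prohibit = prohibited_cells, ...)
}

#' @export
print.opt_design <- function(x, digits = 1, ...) {
  cat(sprintf("Optimal allocation (%d iterations%s)\n", x$iterations,
              if (x$converged) "" else ", NOT converged"))
  cat(format_allocation(x$allocation, percent = TRUE, digits = digits))
  cat(sprintf("var(theta_hat) = %.6g sigma^2\n", x$variance$variance))
  invisible(x)
}

#' @export
summary.opt_design <- function(object, ...) {
  s <- list(
    variance = object$variance,
    vtilde = object$vtilde,
    iterations = object$iterations,
    converged = object$converged,
    fixres = object$fixres,
    n_support = sum(object$support, na.rm = TRUE),
    n_cells = nrow(object$layout$cells),
    scale = object$scale, cac = object$cac
  )
  class(s) <- "summary.opt_design"
  s
}

#' @export
print.summary.opt_design <- function(x, ...) {
  cat("Optimal design summary\n")
  print(x$cac); print(x$scale)
  cat(sprintf("  support: %d of %d cells (proportions >= 1e-5)\n",
              x$n_support, x$n_cells))
  cat(sprintf("  var(theta_hat) = %.6g sigma^2 (cluster %.4g + residual %.4g)\n",
              x$variance$variance, x$variance$cluster_term, x$variance$residual_term))
  cat(sprintf("  converged: %s after %d iterations (fixed-point residual %.2e)\n",
              x$converged, x$iterations, x$fixres))
  invisible(x)
}

#' @export
coef.opt_design <- function(object, ...) object$coefficients

#' @export
as.matrix.opt_design <- function(x, ...) x$allocation

#' @export
plot.opt_design <- function(x, ...) {
  pim <- x$allocation
  K <- nrow(pim); T <- ncol(pim)
  graphics::image(seq_len(T), seq_len(K), t(pim[K:1, , drop = FALSE]),
                  col = grDevices::gray.colors(32, start = 1, end = 0.2),
                  xlab = "epoch", ylab = "cluster-sequence", axes = FALSE, ...)
  graphics::axis(1, at = seq_len(T)); graphics::axis(2, at = seq_len(K), labels = K:1)
  graphics::box()
  invisible(x)
}

#' Round a continuous allocation to integer cell counts
#'
#' Converts design proportions to integer numbers of observations summing
#' exactly to `N`. Two rules are available: `"apportionment"`
#' (multiplier/efficient design apportionment: start from
#' `ceiling((N - L/2) * pi)` over the L support cells, then adjust one unit
#' at a time using the quotients `n/pi`) and `"largest_remainder"`
#' (floor plus distribution of the shortfall by descending fractional
#' remainder). All ties are broken deterministically by (k, t) lexicographic
#' order.
#'
#' @param pi allocation matrix (or vector over cells of `layout`).
#' @param N positive integer total.
#' @param layout a [trial_layout()].
#' @param method `"apportionment"` or `"largest_remainder"`.
#' @param min_one require at least one observation in every support cell.
#' @return List with `n` (integer matrix summing to `N`), `N`, and
#'   `realized` (the realized allocation `n/N`).
#' @export
round_design <- function(pi, N, layout, method = c("apportionment", "largest_remainder"),
                         min_one = FALSE) {
  method <- match.arg(method)
  stopifnot(inherits(layout, "trial_layout"))
  if (N != round(N) || N < 1) stop("N must be a positive integer", call. = FALSE)
  pim <- validate_allocation(layout, pi)
  v <- pi_vec(layout, pim)
  supp <- which(v > 0)
  L <- length(supp)
  if (min_one && N < L)
    stop(sprintf("N = %d cannot place one observation in each of %d support cells",
                 N, L), call. = FALSE)
  w <- v[supp]
  # deterministic order: cells are already sorted by (k, t)
  if (max(abs(N * w - round(N * w))) < 1e-9) {
    n_supp <- round(N * w)
  } else if (method == "largest_remainder") {
    base <- floor(N * w)
    rem <- N * w - base
    short <- N - sum(base)
    if (short > 0) {
      ord <- order(-rem, seq_along(rem))
      base[ord[seq_len(short)]] <- base[ord[seq_len(short)]] + 1
    }
    n_supp <- base
  } else {
    n_supp <- ceiling((N - L / 2) * w)
    if (min_one) n_supp <- pmax(n_supp, 1)
    while (sum(n_supp) < N) {
      q <- n_supp / w
      j <- which(q == min(q))[1]
      n_supp[j] <- n_supp[j] + 1
    }
    while (sum(n_supp) > N) {
      q <- (n_supp - 1) / w
      cand <- which(!min_one | n_supp > 1)
      j <- cand[which(q[cand] == max(q[cand]))]
      j <- j[length(j)]
      n_supp[j] <- n_supp[j] - 1
    }
  }
  nv <- numeric(length(v)); nv[supp] <- n_supp
  nmat <- pi_mat(layout, nv)
  list(n = nmat, N = N, realized = nmat / N)
}
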