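#' Cluster-autocorrelation models of the two-parameter family
#'
#' The cluster-period random effects within a cluster follow a Toeplitz
#' correlation matrix `Gamma[s, t] = alpha * r^|s-t| + (1-alpha) * (s == t)`.
#' Special cases: exchangeable (EXC, `alpha = r = 1`, all correlations equal),
#' block-exchangeable (BEX, `r = 1`, constant off-diagonal `alpha`), and
#' discrete-time decay (DTD, `alpha = 1`, geometric decay `r^|s-t|`). If
#' `alpha * r = 0` the matrix is the identity and cluster-periods are
#' uncorrelated. The matrix is invertible for all parameter values in the
#' unit square except the EXC corner.
#'
#' @param alpha within-cluster proportion parameter, in \[0, 1\].
#' @param r decay parameter, in \[0, 1\].
#' @return An object of class `cac_model` with fields `alpha`, `r` and a
#'   `family` tag.
#' @examples
#' cac_bex(0.7)       # block-exchangeable, alpha = 0.7
#' cac_dtd(0.9)       # discrete-time decay, r = 0.9
#' cac_exc()          # exchangeable
#' @export
cac_model <- function(alpha, r) {
  if (!is.numeric(alpha) || !is.numeric(r) || length(alpha) != 1 || length(r) != 1 ||
      is.na(alpha) || is.na(r) || alpha < 0 || alpha > 1 || r < 0 || r > 1)
    stop("cluster-autocorrelation parameters must lie in [0, 1]", call. = FALSE)
  family <- if (alpha == 1 && r == 1) "EXC"
            else if (r == 1) "BEX"
            else if (alpha == 1) "DTD"
            else if (alpha == 0 || r == 0) "IND"
            else "general"
  structure(list(alpha = alpha, r = r, family = family), class = "cac_model")
}

#' @rdname cac_model
#' @export
cac_exc <- function() cac_model(1, 1)

#' @rdname cac_model
#' @export
cac_bex <- function(alpha) cac_model(alpha, 1)

#' @rdname cac_model
#' @export
cac_dtd <- function(r) cac_model(1, r)

#' Wrap a raw correlation matrix as a cluster-autocorrelation model
#'
#' Accepts an arbitrary symmetric correlation matrix for the cluster-period
#' effects, outside the two-parameter family. No estimation from data is
#' provided.
#'
#' @param M symmetric correlation matrix with unit diagonal.
#' @export
cac_matrix <- function(M) {
  M <- as.matrix(M)
  if (nrow(M) != ncol(M) || max(abs(M - t(M))) > 1e-10 ||
      max(abs(diag(M) - 1)) > 1e-10)
    stop("a raw CAC matrix must be symmetric with unit diagonal", call. = FALSE)
  structure(list(M = M, family = "matrix"), class = "cac_model")
}

#' @export
print.cac_model <- function(x, ...) {
  if (x$family == "matrix")
    cat(sprintf("CAC model: raw %dx%d correlation matrix\n", nrow(x$M), ncol(x$M)))
  else
    cat(sprintf("CAC model (%s): alpha = %g, r = %g\n", x$family, x$alpha, x$r))
  invisible(x)
}

#' Cluster-autocorrelation matrix
#'
#' Builds the T x T Toeplitz matrix of cluster autocorrelations for a
#' [cac_model()] (or returns the stored matrix for a raw-matrix model,
#' checking the dimension).
#'
#' @param cac a [cac_model()]; numeric `c(alpha, r)` is also accepted.
#' @param T dimension (number of time-epochs).
#' @export
gamma_matrix <- function(cac, T) {
  if (is.numeric(cac) && length(cac) == 2) cac <- cac_model(cac[1], cac[2])
  stopifnot(inherits(cac, "cac_model"))
  if (!is.numeric(T) || length(T) != 1 || T < 1 || T != round(T))
    stop("T must be a positive integer", call. = FALSE)
  if (cac$family == "matrix") {
    if (nrow(cac$M) != T)
      stop(sprintf("raw CAC matrix is %dx%d but the layout has %d epochs",
                   nrow(cac$M), ncol(cac$M), T), call. = FALSE)
    return(cac$M)
  }
  D <- abs(outer(seq_len(T), seq_len(T), "-"))
  cac$alpha * cac$r^D + (1 - cac$alpha) * diag(T)
}

#' Index of cluster variation and related reparameterizations
#'
#' The index of cluster variation (ICV) is `S = M*rho / (1 + (M-1)*rho)`
#' with `M = N/K` the average cluster size. It is the single scalar through
#' which the total sample size `N` and the intra-cluster correlation `rho`
#' affect the optimal allocation, and equals the cluster-mean correlation.
#' The associated ratio `N*rho/(1-rho)` equals `K*S/(1-S)`.
#'
#' @param N total number of observations in the basic layout.
#' @param K number of cluster-sequences.
#' @param rho intra-cluster correlation, in \[0, 1).
#' @return `icv_from` returns S; `ratio_from_icv` returns `N*rho/(1-rho)`;
#'   `rho_from_icv` inverts the ICV at a given average cluster size `M`.
#' @examples
#' icv_from(2200, 10, 0.05)   # 0.9205 for the 10-cluster, 2200-observation case
#' @export
icv_from <- function(N, K, rho) {
  if (rho < 0 || rho >= 1) stop("rho must lie in [0, 1)", call. = FALSE)
  if (N <= 0 || K <= 0) stop("N and K must be positive", call. = FALSE)
  M <- N / K
  M * rho / (1 + (M - 1) * rho)
}

#' @rdname icv_from
#' @param S index of cluster variation, in \[0, 1).
#' @export
ratio_from_icv <- function(S, K) {
  if (S < 0 || S > 1) stop("S must lie in [0, 1]", call. = FALSE)
  if (S == 1) stop("S = 1 corresponds to an infinite ratio N*rho/(1-rho)", call. = FALSE)
  K * S / (1 - S)
}

#' @rdname icv_from
#' @param M average cluster size `N/K`.
#' @export
rho_from_icv <- function(S, M) {
  if (S < 0 || S >= 1) stop("S must lie in [0, 1)", call. = FALSE)
  if (M <= 0) stop("M must be positive", call. = FALSE)
  S / (M - (M - 1) * S)
}

#' Sample-size scale of a design problem
#'
#' Fixes the sample-size side of the optimization: either the concrete
#' `(N, K, rho)` triple, or the index of cluster variation `S` with `K`, or
#' the raw ratio `N*rho/(1-rho)` with `K`. Exactly one parameterization must
#' be given. Optimal allocations and efficiencies depend on `(N, rho)` only
#' through the ratio; reported variances are in units of the total variance
#' `sigma2` (default 1).
#'
#' When only `S` or `ratio` is supplied, a canonical representative with one
#' observation per cluster (`N = K`, `rho = S`) is stored: every scale-free
#' quantity (allocations, efficiencies, thresholds) is unaffected by this
#' choice.
#'
#' @param N total observations; `K` number of cluster-sequences; `rho` ICC.
#' @param S index of cluster variation.
#' @param ratio the ratio `N*rho/(1-rho)`.
#' @param sigma2 total variance, default 1.
#' @return An object of class `design_scale` with fields `N`, `K`, `rho`,
#'   `M`, `S`, `ratio`, `sigma2`.
#' @export
design_scale <- function(N = NULL, K = NULL, rho = NULL, S = NULL, ratio = NULL,
                         sigma2 = 1) {
  if (is.null(K)) stop("K (number of cluster-sequences) is required", call. = FALSE)
  given <- c(NKrho = !is.null(N) && !is.null(rho), S = !is.null(S),
             ratio = !is.null(ratio))
  if (sum(given) != 1)
    stop("give exactly one of (N, rho), S, or ratio", call. = FALSE)
  if (given["S"]) {
    if (S < 0 || S >= 1) stop("S must lie in [0, 1)", call. = FALSE)
    rho <- S; N <- K
  } else if (given["ratio"]) {
    if (ratio < 0) stop("ratio must be nonnegative", call. = FALSE)
    rho <- ratio / (K + ratio); N <- K
  } else {
    if (rho < 0 || rho >= 1) stop("rho must lie in [0, 1)", call. = FALSE)
    if (N <= 0) stop("N must be positive", call. = FALSE)
  }
  structure(list(N = N, K = K, rho = rho, M = N / K,
                 S = icv_from(N, K, rho), ratio = N * rho / (1 - rho),
                 sigma2 = sigma2),
            class = "design_scale")
}

#' @export
print.design_scale <- function(x, ...) {
  cat(sprintf("Design scale: N = %g, K = %d, rho = %g (S = %.4f, N*rho/(1-rho) = %.4f)\n",
              x$N, x$K, x$rho, x$S, x$ratio))
  invisible(x)
}
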