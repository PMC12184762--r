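#' Experimental layouts for discrete-time cluster studies
#'
#' A trial layout is the set of available cluster-period cells of a K x T
#' lattice, together with the (fixed) treatment status of each cell. Rows are
#' cluster-sequences (one cluster per sequence in the basic layout), columns
#' are time-epochs. Cells absent from the layout (prohibited cells) are
#' represented as `NA` in the treatment matrix, distinct from present cells
#' that happen to receive no observations.
#'
#' @param Z K x T matrix of treatment indicators: 1 where the treated
#'   condition is present, 0 where the control condition is present, and `NA`
#'   for cells that are not part of the layout.
#' @return An object of class `trial_layout` with components `K`, `T`, `Z`
#'   (the indicator matrix, `NA` for absent cells) and `cells` (a data frame
#'   with one row per available cell: `k`, `t`, `Z`, ordered by cluster then
#'   epoch).
#' @details A layout must allow a controlled treatment comparison: at least
#'   one epoch must contain both a treated and a control cell. Every
#'   cluster-sequence must contain at least one cell.
#' @seealso [sw_layout()], [parallel_layout()], [crossover_layout()]
#' @export
trial_layout <- function(Z) {
  Z <- as.matrix(Z)
  if (!all(Z %in% c(0, 1, NA)))
    stop("treatment indicators must be 0, 1 or NA", call. = FALSE)
  K <- nrow(Z)
  T <- ncol(Z)
  if (any(rowSums(!is.na(Z)) == 0))
    stop("every cluster-sequence must contain at least one cell", call. = FALSE)
  has_contrast <- any(apply(Z, 2, function(z) {
    z <- z[!is.na(z)]
    length(z) && any(z == 1) && any(z == 0)
  }))
  if (!has_contrast)
    stop("no treatment contrast: no epoch contains both a treated and a control cell",
         call. = FALSE)
  idx <- which(!is.na(Z), arr.ind = TRUE)
  cells <- data.frame(k = idx[, 1], t = idx[, 2], Z = Z[idx])
  cells <- cells[order(cells$k, cells$t), , drop = FALSE]
  rownames(cells) <- NULL
  structure(list(K = K, T = T, Z = Z, cells = cells), class = "trial_layout")
}

#' Standard stepped-wedge layout
#'
#' The complete K x (K+1) lattice in which cluster-sequence k switches
#' irreversibly from control to treatment at epoch k+1, i.e. `Z[k, t] = 1`
#' iff `t > k`. All clusters are in the control condition at baseline
#' (t = 1) and in the treated condition at endline (t = K+1).
#'
#' @param K number of cluster-sequences (>= 2).
#' @return A [trial_layout()].
#' @examples
#' sw_layout(4)
#' @export
sw_layout <- function(K) {
  if (!is.numeric(K) || length(K) != 1 || K != round(K) || K < 2)
    stop("invalid layout: K must be an integer >= 2", call. = FALSE)
  Z <- outer(seq_len(K), seq_len(K + 1), function(k, t) as.numeric(t > k))
  trial_layout(Z)
}

#' Two-sequence parallel and cross-over layouts
#'
#' Multi-period layouts with K = 2 cluster-sequences. In the parallel layout
#' one sequence is treated throughout and the other is control throughout; in
#' the cross-over layout treatment alternates between epochs with the two
#' sequences out of phase, so every epoch contains both arms.
#'
#' @param T number of time-epochs (parallel: >= 1; cross-over: >= 2).
#' @return A [trial_layout()] with `K = 2`.
#' @examples
#' parallel_layout(3)
#' crossover_layout(4)
#' @export
parallel_layout <- function(T) {
  if (!is.numeric(T) || length(T) != 1 || T != round(T) || T < 1)
    stop("invalid layout: T must be a positive integer", call. = FALSE)
  trial_layout(rbind(rep(1, T), rep(0, T)))
}

#' @rdname parallel_layout
#' @export
crossover_layout <- function(T) {
  if (!is.numeric(T) || length(T) != 1 || T != round(T) || T < 2)
    stop("invalid layout: T must be an integer >= 2", call. = FALSE)
  Z <- outer(1:2, seq_len(T), function(k, t) ((-1)^(k + t) + 1) / 2)
  trial_layout(Z)
}

#' @export
print.trial_layout <- function(x, ...) {
  cat(sprintf("Trial layout: %d cluster-sequence(s) x %d epoch(s), %d cells (%d treated)\n",
              x$K, x$T, nrow(x$cells), sum(x$cells$Z)))
  disp <- matrix(".", x$K, x$T)
  disp[!is.na(x$Z)] <- ifelse(x$Z[!is.na(x$Z)] == 1, "T", "C")
  dimnames(disp) <- list(cluster = seq_len(x$K), epoch = seq_len(x$T))
  print(disp, quote = FALSE)
  invisible(x)
}

#' Uniform allocation over the available cells of a layout
#'
#' @param layout a [trial_layout()].
#' @return A K x T allocation matrix with equal proportions on every
#'   available cell (`NA` on absent cells), summing to 1.
#' @export
uniform_allocation <- function(layout) {
  stopifnot(inherits(layout, "trial_layout"))
  pi <- ifelse(is.na(layout$Z), NA_real_, 1 / nrow(layout$cells))
  pi
}

#' Validate an allocation against a layout
#'
#' An allocation assigns a nonnegative proportion of the total sample to each
#' available cell; the proportions must sum to 1.
#'
#' @param layout a [trial_layout()].
#' @param pi K x T numeric matrix of proportions (`NA` allowed on absent
#'   cells), or a vector over the cells of the layout in `layout$cells`
#'   order.
#' @param tol tolerance for the sum-to-one check.
#' @return The allocation as a validated K x T matrix (invisibly usable).
#' @export
validate_allocation <- function(layout, pi, tol = 1e-8) {
  stopifnot(inherits(layout, "trial_layout"))
  if (!is.matrix(pi)) {
    if (length(pi) != nrow(layout$cells))
      stop("allocation vector length does not match the number of cells", call. = FALSE)
    m <- matrix(NA_real_, layout$K, layout$T)
    m[cbind(layout$cells$k, layout$cells$t)] <- pi
    pi <- m
  }
  if (nrow(pi) != layout$K || ncol(pi) != layout$T)
    stop("allocation matrix dimensions do not match the layout", call. = FALSE)
  vals <- pi[cbind(layout$cells$k, layout$cells$t)]
  if (anyNA(vals))
    stop("allocation is missing on an available cell", call. = FALSE)
  if (any(vals < -tol))
    stop("allocation has negative entries", call. = FALSE)
  off <- pi[is.na(layout$Z)]
  if (length(off) && any(!is.na(off) & off != 0))
    stop("allocation places mass on a cell outside the layout", call. = FALSE)
  s <- sum(vals)
  if (abs(s - 1) > tol)
    stop(sprintf("allocation proportions sum to %.6f, not 1", s), call. = FALSE)
  pi
}

# allocation matrix -> vector in layout$cells order
pi_vec <- function(layout, pi) {
  if (is.matrix(pi)) pi[cbind(layout$cells$k, layout$cells$t)] else pi
}

# vector in layout$cells order -> K x T matrix (NA off layout)
pi_mat <- function(layout, v) {
  m <- matrix(NA_real_, layout$K, layout$T)
  m[cbind(layout$cells$k, layout$cells$t)] <- v
  m
}

#' Skew transformation of a layout or allocation
#'
#' Combines time-reversal (t -> T-t+1) with interchange of treatment status
#' (Z -> 1-Z) and reverse ordering of the cluster-sequences (k -> K-k+1).
#' Stepped-wedge layouts are fixed points of this transformation, and any
#' unique optimal allocation over a stepped-wedge layout is invariant under
#' it (skew-symmetric). Applying the transformation twice is the identity.
#'
#' @param x a [trial_layout()] or an allocation matrix.
#' @return An object of the same type as `x`.
#' @export
skew_transform <- function(x) UseMethod("skew_transform")

#' @export
skew_transform.trial_layout <- function(x) {
  Z <- 1 - x$Z[x$K:1, x$T:1, drop = FALSE]
  trial_layout(Z)
}

#' @export
skew_transform.matrix <- function(x) {
  x[nrow(x):1, ncol(x):1, drop = FALSE]
}

#' @export
skew_transform.default <- function(x) {
  stop("skew_transform is defined for trial_layout objects and matrices", call. = FALSE)
}
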