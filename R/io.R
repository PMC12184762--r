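#' Read and write layouts and allocations
#'
#' Layouts and allocations are exchanged in two dialects. The CSV dialect is
#' a long table with one row per available cell and columns
#' `cluster,period,treated[,proportion]`; ragged (incomplete) layouts are
#' expressible because absent cells simply have no row. The JSON dialect is a
#' matrix object `{"K":..,"T":..,"Z":[[..]],"mask":[[..]],"pi":[[..]]}` where
#' `mask` marks available cells and `pi` is optional. All indices are 1-based.
#'
#' @param path file to read or write; dialect is chosen by extension
#'   (`.json` for JSON, anything else is treated as CSV).
#' @return `read_layout` returns a [trial_layout()]; `read_allocation`
#'   returns a list with components `layout` and `pi` (K x T matrix).
#' @name layout_io
NULL

read_layout_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cluster", "period", "treated")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(sprintf("layout file is missing column(s): %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  bad <- which(!is.finite(df$cluster) | !is.finite(df$period) |
                 df$cluster != round(df$cluster) | df$period != round(df$period) |
                 df$cluster < 1 | df$period < 1 | !(df$treated %in% c(0, 1)))
  if (length(bad))
    stop(sprintf("malformed layout rows: %s", paste(utils::head(bad, 5), collapse = ", ")),
         call. = FALSE)
  dup <- duplicated(df[c("cluster", "period")])
  if (any(dup))
    stop(sprintf("duplicate cells at rows: %s",
                 paste(utils::head(which(dup), 5), collapse = ", ")), call. = FALSE)
  K <- max(df$cluster); T <- max(df$period)
  Z <- matrix(NA_real_, K, T)
  Z[cbind(df$cluster, df$period)] <- df$treated
  layout <- trial_layout(Z)
  pi <- NULL
  if ("proportion" %in% names(df)) {
    pi <- matrix(NA_real_, K, T)
    pi[cbind(df$cluster, df$period)] <- df$proportion
  }
  list(layout = layout, pi = pi)
}

read_layout_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$Z)) stop("layout JSON is missing the Z matrix", call. = FALSE)
  Z <- as.matrix(obj$Z)
  if (!is.null(obj$mask)) {
    mask <- as.matrix(obj$mask)
    Z[!(mask > 0)] <- NA
  }
  layout <- trial_layout(Z)
  pi <- if (!is.null(obj$pi)) as.matrix(obj$pi) else NULL
  if (!is.null(pi)) pi[is.na(layout$Z)] <- NA
  list(layout = layout, pi = pi)
}

#' @rdname layout_io
#' @export
read_layout <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) read_layout_json(path)$layout
  else read_layout_csv(path)$layout
}

#' @rdname layout_io
#' @param layout a [trial_layout()].
#' @export
write_layout <- function(layout, path) {
  stopifnot(inherits(layout, "trial_layout"))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- list(K = layout$K, T = layout$T,
                Z = ifelse(is.na(layout$Z), 0, layout$Z),
                mask = 1 * !is.na(layout$Z))
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  } else {
    df <- data.frame(cluster = layout$cells$k, period = layout$cells$t,
                     treated = layout$cells$Z)
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname layout_io
#' @export
read_allocation <- function(path) {
  res <- if (grepl("\\.json$", path, ignore.case = TRUE)) read_layout_json(path)
         else read_layout_csv(path)
  if (is.null(res$pi))
    stop("file contains no allocation (proportion column or pi matrix)", call. = FALSE)
  res$pi <- validate_allocation(res$layout, res$pi)
  res
}

#' @rdname layout_io
#' @param pi K x T allocation matrix.
#' @export
write_allocation <- function(layout, pi, path) {
  pi <- validate_allocation(layout, pi)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- list(K = layout$K, T = layout$T,
                Z = ifelse(is.na(layout$Z), 0, layout$Z),
                mask = 1 * !is.na(layout$Z),
                pi = ifelse(is.na(pi), 0, pi))
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  } else {
    df <- data.frame(cluster = layout$cells$k, period = layout$cells$t,
                     treated = layout$cells$Z,
                     proportion = pi[cbind(layout$cells$k, layout$cells$t)])
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}
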