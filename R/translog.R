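#' Translog coefficient layout
#'
#' Defines the ordered parameter vector of a translog cost frontier with
#' linear homogeneity imposed by normalizing cost and prices by the last
#' input price (labour). For `n_outputs` outputs and `n_prices` normalized
#' price ratios the layout holds, in order: the intercept `beta0`;
#' first-order output terms `beta1..betaJ`; first-order price terms
#' `delta1..deltaS`; output squares and cross-products `betajk` for
#' `j <= k` (symmetry stored once); price squares/cross-products `deltasr`
#' for `s <= r`; and output-by-price interactions `rhojs`.
#'
#' The study specification has 5 outputs and 2 normalized prices (3 raw
#' prices with labour as numeraire), giving 36 parameters:
#' 1 + 5 + 2 + 15 + 3 + 10.
#'
#' @param n_outputs Number of outputs J (default 5).
#' @param n_prices Number of normalized price ratios S (default 2; i.e.
#'   S + 1 raw input prices with the last as numeraire).
#' @return An object of class `translog_layout`: a list with `names`
#'   (ordered parameter names), `index` (named integer map), `terms`
#'   (per-term type and variable indices), `n_outputs`, `n_prices`, `p`.
#' @export
#' @examples
#' lay <- translog_layout()
#' lay$p            # 36
#' head(lay$names)  # "beta0" "beta1" ...
translog_layout <- function(n_outputs = 5L, n_prices = 2L) {
  J <- as.integer(n_outputs); S <- as.integer(n_prices)
  if (J < 1L || S < 1L) stop("need at least one output and one normalized price")
  nm <- "beta0"
  type <- "intercept"; i1 <- 0L; i2 <- 0L
  add <- function(n, t, a, b) {
    nm <<- c(nm, n); type <<- c(type, t); i1 <<- c(i1, a); i2 <<- c(i2, b)
  }
  for (j in seq_len(J)) add(paste0("beta", j), "x", j, 0L)
  for (s in seq_len(S)) add(paste0("delta", s), "w", s, 0L)
  for (j in seq_len(J)) for (k in j:J)
    add(paste0("beta", j, k), "xx", j, k)
  for (s in seq_len(S)) for (r in s:S)
    add(paste0("delta", s, r), "ww", s, r)
  for (j in seq_len(J)) for (s in seq_len(S))
    add(paste0("rho", j, s), "xw", j, s)
  p <- length(nm)
  stopifnot(p == 1L + J + S + J * (J + 1L) / 2L + S * (S + 1L) / 2L + J * S)
  structure(list(
    names = nm,
    index = stats::setNames(seq_len(p), nm),
    terms = data.frame(name = nm, type = type, i1 = i1, i2 = i2,
                       stringsAsFactors = FALSE),
    n_outputs = J, n_prices = S, p = p
  ), class = "translog_layout")
}

#' @export
print.translog_layout <- function(x, ...) {
  cat(sprintf("translog layout: %d outputs, %d normalized prices, %d parameters\n",
              x$n_outputs, x$n_prices, x$p))
  invisible(x)
}

#' Build one translog design row
#'
#' Maps log outputs and log normalized prices to the 36-term (or reduced)
#' regressor vector. Diagonal second-order entries carry the 1/2 factor of
#' the translog expansion; off-diagonal pairs are stored once and carry the
#' combined factor (1/2 x 2 = 1), so the stored coefficient equals the
#' symmetric-sum coefficient reported in frontier tables.
#'
#' @param layout A [translog_layout()].
#' @param logx Numeric vector of length `layout$n_outputs`: ln of outputs.
#' @param logw Numeric vector of length `layout$n_prices`: ln of price
#'   ratios w_s / w_numeraire.
#' @return Numeric vector of length `layout$p` named by `layout$names`.
#' @export
build_design_row <- function(layout, logx, logw) {
  stopifnot(inherits(layout, "translog_layout"))
  if (length(logx) != layout$n_outputs || length(logw) != layout$n_prices)
    stop("logx/logw lengths do not match the layout")
  if (!all(is.finite(c(logx, logw)))) stop("non-finite log inputs")
  drop(build_design_matrix(layout, matrix(logx, nrow = 1),
                           matrix(logw, nrow = 1)))
}

#' Build the translog design matrix for many observations
#'
#' Vectorized form of [build_design_row()]: each row of `logx` / `logw` is
#' one hospital-year observation.
#'
#' @param layout A [translog_layout()].
#' @param logx Numeric matrix (n x J) of log outputs.
#' @param logw Numeric matrix (n x S) of log normalized prices.
#' @return Numeric matrix (n x p) with columns named by `layout$names`.
#' @export
build_design_matrix <- function(layout, logx, logw) {
  stopifnot(inherits(layout, "translog_layout"))
  logx <- as.matrix(logx); logw <- as.matrix(logw)
  if (ncol(logx) != layout$n_outputs || ncol(logw) != layout$n_prices)
    stop("logx/logw column counts do not match the layout")
  if (nrow(logx) != nrow(logw)) stop("logx and logw row counts differ")
  if (!all(is.finite(logx)) || !all(is.finite(logw)))
    stop("non-finite log inputs")
  n <- nrow(logx)
  Z <- matrix(0, n, layout$p, dimnames = list(NULL, layout$names))
  tt <- layout$terms
  for (c in seq_len(layout$p)) {
    Z[, c] <- switch(tt$type[c],
      intercept = 1,
      x  = logx[, tt$i1[c]],
      w  = logw[, tt$i1[c]],
      xx = if (tt$i1[c] == tt$i2[c]) 0.5 * logx[, tt$i1[c]]^2
           else logx[, tt$i1[c]] * logx[, tt$i2[c]],
      ww = if (tt$i1[c] == tt$i2[c]) 0.5 * logw[, tt$i1[c]]^2
           else logw[, tt$i1[c]] * logw[, tt$i2[c]],
      xw = logx[, tt$i1[c]] * logw[, tt$i2[c]]
    )
  }
  Z
}

#' Evaluate the deterministic frontier
#'
#' Inner product of a design row (or matrix) with a coefficient vector,
#' giving the frontier value of ln(C / w_numeraire) without the composed
#' error.
#'
#' @param row Design row (length p) or matrix (n x p).
#' @param theta Coefficient vector of length p.
#' @return Numeric scalar or vector of predicted log normalized cost.
#' @export
predict_log_cost <- function(row, theta) {
  if (is.matrix(row)) {
    if (ncol(row) != length(theta)) stop("row/theta length mismatch")
    drop(row %*% theta)
  } else {
    if (length(row) != length(theta)) stop("row/theta length mismatch")
    sum(row * theta)
  }
}

#' Check linear homogeneity in input prices
#'
#' Verifies that predicted cost scales exactly by `lambda` when all raw
#' input prices are scaled by `lambda`. This holds for every coefficient
#' vector by construction of the normalization (cost and prices divided by
#' the numeraire price), so the check is a structural sanity test.
#'
#' @param layout A [translog_layout()].
#' @param logx Log outputs (length J).
#' @param prices Raw input prices (length S + 1; last is the numeraire).
#' @param theta Coefficient vector (length p).
#' @param lambda Positive scale factor.
#' @param tol Relative tolerance.
#' @return `TRUE` if homogeneity holds to `tol`.
#' @export
check_homogeneity <- function(layout, logx, prices, theta, lambda,
                              tol = 1e-10) {
  if (lambda <= 0) stop("lambda must be positive")
  if (any(prices <= 0)) stop("prices must be positive")
  S <- layout$n_prices
  if (length(prices) != S + 1L) stop("need S + 1 raw prices")
  cost_at <- function(w) {
    lw <- log(w[seq_len(S)] / w[S + 1L])
    w[S + 1L] * exp(predict_log_cost(build_design_row(layout, logx, lw), theta))
  }
  c1 <- cost_at(prices)
  c2 <- cost_at(lambda * prices)
  abs(c2 - lambda * c1) <= tol * max(1, abs(lambda * c1))
}

#' Export the coefficient layout as a JSON name-to-index map
#'
#' @param layout A [translog_layout()].
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @return JSON string (invisibly if written to file).
#' @export
layout_to_json <- function(layout, path = NULL) {
  j <- jsonlite::toJSON(as.list(layout$index), auto_unbox = TRUE, pretty = TRUE)
  if (!is.null(path)) { writeLines(j, path); return(invisible(j)) }
  j
}
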