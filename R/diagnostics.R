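#' Effective sample size of a single chain
#'
#' `n / (1 + 2 * sum(rho_k))` with the autocorrelation sum truncated at
#' the first nonpositive estimate (initial-positive-sequence rule). A
#' constant chain has no information and returns `NA`.
#'
#' @param x Numeric draw vector.
#' @return Estimated effective sample size (capped at `length(x)`).
#' @export
effective_sample_size <- function(x) {
  n <- length(x)
  if (n < 3L || stats::var(x) == 0) return(NA_real_)
  rho <- stats::acf(x, lag.max = min(n - 1L, 10 * floor(log10(n)) * 10L),
                    plot = FALSE)$acf[-1L]
  pos <- which(rho <= 0)
  if (length(pos)) rho <- rho[seq_len(pos[1L] - 1L)]
  min(n, n / (1 + 2 * sum(rho)))
}

#' Single-chain convergence summary
#'
#' For each parameter column: effective sample size and a split-half
#' mean-comparison z-score (first versus second half of the retained
#' draws, standard errors scaled by each half's effective sample size).
#' Parameters with |z| > 3, or with no variation at all, are flagged.
#'
#' @param draws Matrix of retained draws (iterations x parameters), e.g.
#'   from [parameter_draws()].
#' @param params Optional character or integer subset of columns.
#' @return Data frame with columns `param`, `ess`, `z`, `flag`.
#' @export
convergence_summary <- function(draws, params = NULL) {
  draws <- as.matrix(draws)
  if (nrow(draws) < 100L) stop("need at least 100 retained draws")
  if (!is.null(params)) draws <- draws[, params, drop = FALSE]
  nm <- colnames(draws)
  if (is.null(nm)) nm <- paste0("par", seq_len(ncol(draws)))
  half <- nrow(draws) %/% 2L
  res <- lapply(seq_len(ncol(draws)), function(j) {
    x <- draws[, j]
    ess <- effective_sample_size(x)
    a <- x[seq_len(half)]; b <- x[(half + 1L):nrow(draws)]
    if (is.na(ess) || stats::var(a) == 0 || stats::var(b) == 0) {
      z <- NA_real_; flag <- TRUE
    } else {
      essa <- effective_sample_size(a); essb <- effective_sample_size(b)
      if (is.na(essa)) essa <- 1; if (is.na(essb)) essb <- 1
      se2 <- stats::var(a) / essa + stats::var(b) / essb
      z <- (mean(a) - mean(b)) / sqrt(se2)
      flag <- abs(z) > 3
    }
    data.frame(param = nm[j], ess = ess, z = z, flag = flag,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
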