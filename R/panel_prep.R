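#' Deflate a nominal monetary value to a base-year price level
#'
#' Applies a consumer-price-index deflator: `nominal * index_base /
#' index_year`. Used to express hospital costs and input prices at constant
#' (base-2021 in the study design) prices.
#'
#' @param nominal Nominal monetary value(s).
#' @param index_year CPI value of the observation year (positive).
#' @param index_base CPI value of the base year (positive).
#' @return Deflated value(s), same length as `nominal`.
#' @export
#' @examples
#' deflate_monetary(100, 80, 100)  # 125
deflate_monetary <- function(nominal, index_year, index_base) {
  if (any(!is.finite(index_year)) || any(!is.finite(index_base)) ||
      any(index_year <= 0) || any(index_base <= 0))
    stop("price indices must be positive and finite")
  nominal * (index_base / index_year)
}

#' Case-mix weight hospital discharges
#'
#' Multiplies raw discharges by the hospital's case-mix index (average DRG
#' weight), making activity comparable across hospitals with different
#' patient complexity.
#'
#' @param discharges Nonnegative raw discharge count(s).
#' @param case_mix_index Positive case-mix index (average DRG weight).
#' @return Weighted discharges.
#' @export
case_mix_adjust <- function(discharges, case_mix_index) {
  if (any(discharges < 0)) stop("discharges must be nonnegative")
  if (any(!is.finite(case_mix_index)) || any(case_mix_index <= 0))
    stop("case-mix index must be positive")
  discharges * case_mix_index
}

#' Read a hospital-year panel from CSV
#'
#' Expects header columns `hospital_id, year, cost, x1..xJ, w1..wK`
#' (K raw prices, the last being the numeraire/labour price). Optional
#' columns `discharges_raw`, `case_mix_index`, `cpi_index` are carried
#' through for auditing.
#'
#' @param path CSV file path (UTF-8, decimal point).
#' @param n_outputs Number of output columns expected (default 5).
#' @param n_raw_prices Number of raw price columns expected (default 3).
#' @return A `hospital_panel`: data.frame with validated column set.
#' @export
read_panel <- function(path, n_outputs = 5L, n_raw_prices = 3L) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  as_hospital_panel(df, n_outputs = n_outputs, n_raw_prices = n_raw_prices)
}

#' Coerce a data.frame to a hospital panel
#'
#' @param df Data frame with columns `hospital_id`, `year`, `cost`,
#'   `x1..xJ`, `w1..wK`.
#' @param n_outputs Number of outputs J.
#' @param n_raw_prices Number of raw input prices K (last is numeraire).
#' @return A data.frame of class `hospital_panel` with attributes
#'   `n_outputs`, `n_raw_prices`.
#' @export
as_hospital_panel <- function(df, n_outputs = 5L, n_raw_prices = 3L) {
  need <- c("hospital_id", "year", "cost",
            paste0("x", seq_len(n_outputs)), paste0("w", seq_len(n_raw_prices)))
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("panel is missing columns: ", paste(miss, collapse = ", "))
  df <- as.data.frame(df)
  attr(df, "n_outputs") <- as.integer(n_outputs)
  attr(df, "n_raw_prices") <- as.integer(n_raw_prices)
  class(df) <- c("hospital_panel", "data.frame")
  df
}

#' Validate a hospital panel
#'
#' Checks key uniqueness, positivity of costs and prices, nonnegative
#' outputs (strictly positive where logs are taken, including the
#' satisfaction score), finiteness, and reports hospitals with missing
#' years (unbalanced panels are accepted, only reported).
#'
#' @param panel A `hospital_panel` (see [as_hospital_panel()]).
#' @return A list of class `panel_validation`: `pass` (logical) and
#'   `issues` (data.frame with columns `severity`, `hospital_id`, `year`,
#'   `issue`). Only `error`-severity issues fail the panel.
#' @export
validate_panel <- function(panel) {
  stopifnot(inherits(panel, "hospital_panel"))
  J <- attr(panel, "n_outputs"); K <- attr(panel, "n_raw_prices")
  iss <- list()
  add <- function(sev, id, yr, what)
    iss[[length(iss) + 1L]] <<- data.frame(severity = sev,
      hospital_id = as.character(id), year = as.integer(yr), issue = what,
      stringsAsFactors = FALSE)

  key <- paste(panel$hospital_id, panel$year, sep = "\r")
  dup <- unique(key[duplicated(key)])
  for (d in dup) {
    parts <- strsplit(d, "\r", fixed = TRUE)[[1]]
    add("error", parts[1], parts[2], "duplicated (hospital_id, year) key")
  }

  num_cols <- c("cost", paste0("x", seq_len(J)), paste0("w", seq_len(K)))
  for (i in seq_len(nrow(panel))) {
    id <- panel$hospital_id[i]; yr <- panel$year[i]
    vals <- unlist(panel[i, num_cols])
    if (any(!is.finite(vals))) {
      add("error", id, yr, "non-finite or missing value")
      next
    }
    if (panel$cost[i] <= 0) add("error", id, yr, "nonpositive cost")
    for (s in seq_len(K)) if (panel[[paste0("w", s)]][i] <= 0)
      add("error", id, yr, sprintf("nonpositive price w%d", s))
    for (j in seq_len(J)) {
      xv <- panel[[paste0("x", j)]][i]
      if (xv < 0) add("error", id, yr, sprintf("negative output x%d", j))
      else if (xv == 0)
        add("error", id, yr, sprintf("zero output x%d (log undefined)", j))
    }
  }

  yrs <- sort(unique(panel$year))
  for (h in unique(panel$hospital_id)) {
    have <- panel$year[panel$hospital_id == h]
    gone <- setdiff(yrs, have)
    for (g in gone) add("note", h, g, "missing year (unbalanced panel)")
  }

  issues <- if (length(iss)) do.call(rbind, iss) else
    data.frame(severity = character(), hospital_id = character(),
               year = integer(), issue = character(), stringsAsFactors = FALSE)
  structure(list(pass = !any(issues$severity == "error"), issues = issues),
            class = "panel_validation")
}

#' @export
print.panel_validation <- function(x, ...) {
  cat(sprintf("panel validation: %s (%d issue(s), %d error(s))\n",
              if (x$pass) "PASS" else "FAIL", nrow(x$issues),
              sum(x$issues$severity == "error")))
  if (nrow(x$issues)) print(utils::head(x$issues, 20))
  invisible(x)
}

#' Transform a panel to model-ready rows
#'
#' Imposes linear homogeneity in input prices by normalizing by the last
#' (labour) price: the response is `y = ln(cost / wK)` and prices enter as
#' `ln(ws / wK)`, s = 1..K-1. Outputs enter as `ln(xj)`.
#'
#' @param panel A validated `hospital_panel`.
#' @return A data.frame of class `model_rows` with columns `hospital_id`,
#'   `year`, `hospital_index`, `year_index`, `y`, `logx1..logxJ`,
#'   `logw1..logwS` (S = K - 1); attributes `n_outputs`, `n_prices`.
#' @export
to_model_rows <- function(panel) {
  stopifnot(inherits(panel, "hospital_panel"))
  v <- validate_panel(panel)
  if (!v$pass) {
    bad <- v$issues[v$issues$severity == "error", , drop = FALSE]
    stop("invalid panel: ", paste(sprintf("[%s/%s] %s", bad$hospital_id,
         bad$year, bad$issue), collapse = "; "))
  }
  J <- attr(panel, "n_outputs"); K <- attr(panel, "n_raw_prices")
  S <- K - 1L
  wK <- panel[[paste0("w", K)]]
  out <- data.frame(
    hospital_id = panel$hospital_id,
    year = panel$year,
    hospital_index = match(panel$hospital_id, unique(panel$hospital_id)),
    year_index = match(panel$year, sort(unique(panel$year))),
    y = log(panel$cost) - log(wK),
    stringsAsFactors = FALSE)
  for (j in seq_len(J)) out[[paste0("logx", j)]] <- log(panel[[paste0("x", j)]])
  for (s in seq_len(S))
    out[[paste0("logw", s)]] <- log(panel[[paste0("w", s)]]) - log(wK)
  attr(out, "n_outputs") <- J
  attr(out, "n_prices") <- S
  class(out) <- c("model_rows", "data.frame")
  out
}

#' Assemble the estimation frame (response, design matrix, grouping)
#'
#' By default the log outputs and log price ratios are centered at their
#' sample means before the translog expansion — the standard approximation
#' point, under which first-order coefficients are cost elasticities at
#' the sample mean and the second-order columns are far better
#' conditioned. Centering only reparameterizes the frontier (predictions
#' and efficiency are unchanged).
#'
#' @param rows A `model_rows` data.frame from [to_model_rows()].
#' @param layout Optional [translog_layout()]; defaults to one matching the
#'   row dimensions.
#' @param center `TRUE` (center at sample means, default), `FALSE` (raw
#'   logs), or a numeric vector of length J + S giving explicit centers
#'   for `logx1..logxJ, logw1..logwS`.
#' @return List with `y`, `Z` (n x p design), `hospital` (integer index),
#'   `hospital_id`, `year`, `layout`, `centers` (the log-scale centers
#'   used, zero when `center = FALSE`).
#' @export
model_frame <- function(rows, layout = NULL, center = TRUE) {
  stopifnot(inherits(rows, "model_rows"))
  J <- attr(rows, "n_outputs"); S <- attr(rows, "n_prices")
  if (is.null(layout)) layout <- translog_layout(J, S)
  if (layout$n_outputs != J || layout$n_prices != S)
    stop("layout dimensions do not match the model rows")
  logx <- as.matrix(rows[paste0("logx", seq_len(J))])
  logw <- as.matrix(rows[paste0("logw", seq_len(S))])
  centers <- if (isTRUE(center)) c(colMeans(logx), colMeans(logw))
    else if (identical(center, FALSE)) numeric(J + S)
    else { stopifnot(length(center) == J + S); as.numeric(center) }
  logx <- sweep(logx, 2L, centers[seq_len(J)])
  logw <- sweep(logw, 2L, centers[J + seq_len(S)])
  list(y = rows$y,
       Z = build_design_matrix(layout, logx, logw),
       hospital = rows$hospital_index,
       hospital_id = rows$hospital_id,
       year = rows$year,
       layout = layout,
       centers = centers)
}
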