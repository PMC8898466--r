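# Fixed z quantile for the default 95% interval (qnorm(0.975) to the
# precision used throughout).
Z_95 <- 1.959964

checkCells <- function(a, b, c, d) {
  cells <- cbind(a = a, b = b, c = c, d = d)
  if (any(cells < 0) || any(!is.finite(cells)))
    stopConfig("contingency cells must be finite and non-negative")
  zero <- colnames(cells)[apply(cells == 0, 2, any)]
  if (length(zero))
    stopCondition("faersignalUndefinedROR",
                  sprintf("undefined ROR: zero cell(s) %s (enable the Haldane-Anscombe correction or report as undefined)",
                          paste(zero, collapse = ", ")))
  invisible(NULL)
}

#' Reporting odds ratio from a 2x2 contingency table
#'
#' The ROR contrasts the odds of reporting the event of interest (versus
#' any other adverse event) for the target drug against the same odds for
#' the comparator: `(a/b) / (c/d) = (a*d) / (b*c)`, with `a` = target
#' cases with the event, `b` = target cases without, `c`/`d` the
#' comparator analogues.
#'
#' @param a,b,c,d Non-negative cell counts (vectorised).
#' @param correction Apply the Haldane-Anscombe +0.5 continuity
#'   correction to all four cells.  With `correction = FALSE` (default)
#'   any zero cell raises an undefined-ROR error naming the cell.
#' @return Positive numeric vector of RORs.
#' @export
#' @examples
#' rorEstimate(20, 80, 10, 90)  # 2.25
rorEstimate <- function(a, b, c, d, correction = FALSE) {
  if (correction) {
    a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
  } else {
    checkCells(a, b, c, d)
  }
  (a * d) / (b * c)
}

#' Woolf confidence interval for a reporting odds ratio
#'
#' Log-normal interval `exp(ln ROR -+ z * sqrt(1/a + 1/b + 1/c + 1/d))`,
#' the de-facto standard interval in ROR-based pharmacovigilance.
#'
#' @inheritParams rorEstimate
#' @param level Confidence level; at the default 0.95 the z quantile is
#'   fixed at 1.959964.
#' @return A list with `ror`, `ci_low`, `ci_high`.
#' @export
#' @examples
#' rorCI(20, 80, 10, 90)  # ror 2.25, CI approximately (0.994, 5.092)
rorCI <- function(a, b, c, d, level = 0.95, correction = FALSE) {
  ror <- rorEstimate(a, b, c, d, correction = correction)
  if (correction) {
    a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
  }
  z <- if (identical(level, 0.95)) Z_95 else stats::qnorm((1 + level) / 2)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  list(ror = ror, ci_low = exp(log(ror) - z * se),
       ci_high = exp(log(ror) + z * se))
}

#' Classify a disproportionality signal
#'
#' The signal rule used throughout: disproportionate reporting is flagged
#' when the ROR is at least 2.0 with at least 3 cases.  A signal flags
#' disproportionate reporting, not causation.
#'
#' @param ror Positive ROR point estimate(s).
#' @param nCases Case count(s), the `a` cell.
#' @param rorThreshold,minCases Signal rule parameters.
#' @return Logical vector.
#' @export
classifySignal <- function(ror, nCases, rorThreshold = 2.0, minCases = 3L) {
  ror >= rorThreshold & nCases >= minCases
}

#' Evaluate signals over a batch of contingency tables
#'
#' Computes ROR, 95% Woolf CI and the signal flag for every table row
#' produced by [buildDesignTables()].  A table with a zero cell under the
#' `"error"` zero-cell policy is marked undefined (NA estimates,
#' `is_signal` NA) without aborting the batch; under `"haldane"` all four
#' cells of such tables get +0.5 and `correction_applied` records it.
#'
#' @param tables data.frame with columns `a`, `b`, `c`, `d` (and
#'   typically `design`, `target`, `comparator`, `event_group`).
#' @param level Confidence level.
#' @param zeroCell `"error"` (mark undefined) or `"haldane"` (+0.5 on all
#'   cells of zero-cell tables).
#' @param rorThreshold,minCases Signal rule parameters.
#' @return The input data.frame, ordered by (design, comparator,
#'   event_group) when those columns exist, with appended columns `ror`,
#'   `ci_low`, `ci_high`, `n_cases`, `is_signal`, `correction_applied`,
#'   `undefined`.
#' @export
evaluateDesigns <- function(tables, level = 0.95,
                            zeroCell = c("error", "haldane"),
                            rorThreshold = 2.0, minCases = 3L) {
  zeroCell <- match.arg(zeroCell)
  stopifnot(all(c("a", "b", "c", "d") %in% names(tables)))
  ordCols <- intersect(c("design", "comparator", "event_group"),
                       names(tables))
  if (length(ordCols))
    tables <- tables[do.call(order, tables[ordCols]), , drop = FALSE]
  n <- nrow(tables)
  ror <- ciLow <- ciHigh <- rep(NA_real_, n)
  corrected <- undefined <- rep(FALSE, n)
  for (i in seq_len(n)) {
    cells <- as.numeric(tables[i, c("a", "b", "c", "d")])
    hasZero <- any(cells == 0)
    if (hasZero && zeroCell == "error") {
      undefined[i] <- TRUE
      next
    }
    corr <- hasZero && zeroCell == "haldane"
    est <- rorCI(cells[1], cells[2], cells[3], cells[4], level = level,
                 correction = corr)
    ror[i] <- est$ror
    ciLow[i] <- est$ci_low
    ciHigh[i] <- est$ci_high
    corrected[i] <- corr
  }
  out <- tables
  out$ror <- ror
  out$ci_low <- ciLow
  out$ci_high <- ciHigh
  out$n_cases <- tables$a
  out$is_signal <- ifelse(undefined, NA,
                          classifySignal(ror, tables$a,
                                         rorThreshold = rorThreshold,
                                         minCases = minCases))
  out$correction_applied <- corrected
  out$undefined <- undefined
  rownames(out) <- NULL
  out
}
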