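# Ear-scoring statistics: the two-tailed exact test on 2x2 kernel tables,
# the barrier-strength odds ratio, the two-tier ear classification,
# recombinant cosegregation, and exact-binomial outlier flagging for the
# open-pollinated screen.

# Normalise an ear argument to c(yellow, purple) counts. Accepts a length-2
# numeric (yellow first) or a one-row data.frame with n_yellow/n_purple.
.ear_counts <- function(x, what = "ear") {
  if (is.data.frame(x)) {
    if (nrow(x) != 1L || !all(c("n_yellow", "n_purple") %in% names(x))) {
      stop(what, " must be a single ear row with n_yellow and n_purple columns")
    }
    x <- c(x$n_yellow, x$n_purple)
  }
  if (!is.numeric(x) || length(x) != 2L || anyNA(x) || any(x < 0)) {
    stop(what, " counts must be two nonnegative numbers (yellow, purple)")
  }
  x
}

#' Two-tailed exact test on a 2x2 contingency table
#'
#' Conditional on both margins, the p-value is the sum of hypergeometric
#' probabilities of every table with the same margins whose point probability
#' does not exceed that of the observed table (the conventional two-sided
#' Fisher rule). Used to compare the donor composition of a test ear against
#' its control ear.
#'
#' @param a,b,c,d Nonnegative integer cell counts: test ear `(a, b)` =
#'   (yellow, purple), control ear `(c, d)`. Alternatively `a` may be a 2x2
#'   matrix whose rows are the two ears.
#' @return Two-sided p-value in `(0, 1]`.
#' @examples
#' exact_test_2x2(6, 0, 0, 9)   # 1/5005, the recombinant cosegregation table
#' exact_test_2x2(5, 5, 5, 5)   # 1: observed table is the mode
#' @export
exact_test_2x2 <- function(a, b = NULL, c = NULL, d = NULL) {
  if (is.matrix(a)) {
    if (!all(dim(a) == c(2L, 2L))) stop("table must be 2x2")
    d <- a[2L, 2L]; c <- a[2L, 1L]; b <- a[1L, 2L]; a <- a[1L, 1L]
  }
  cells <- c(a, b, c, d)
  if (!is.numeric(cells) || length(cells) != 4L || anyNA(cells) ||
      any(cells < 0) || any(cells != round(cells))) {
    stop("cell counts must be four nonnegative integers")
  }
  if (sum(cells) == 0) stop("empty table: no observations to test")
  m <- a + b   # row 1 total
  n <- c + d   # row 2 total
  k <- a + c   # column 1 total
  if (m == 0 || n == 0 || k == 0 || (b + d) == 0) {
    return(1)  # a zero margin fixes the table: only one arrangement exists
  }
  x <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(x, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  # relative tolerance guards against ties lost to floating-point rounding
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Barrier strength: odds ratio of test vs. control ear composition
#'
#' The ratio of kernels from `Tcb1-s`-class vs. `tcb1` pollen on the test
#' ear relative to the control `tcb1` ear: `(a/b) / (c/d)` for test counts
#' `(a, b)` and control counts `(c, d)` in (yellow, purple) order. A value
#' of 1.0 indicates no barrier; significantly larger values a functional
#' barrier. When any cell is zero, `correction` is added to all four cells
#' (Haldane-Anscombe) and the result is flagged with attribute `corrected`.
#'
#' @param test,control Length-2 numeric `c(yellow, purple)` or one-row ear
#'   data.frames with `n_yellow`/`n_purple` columns.
#' @param correction Nonnegative additive zero-cell correction. Default 0.5.
#' @return The barrier-strength odds ratio (attribute `corrected` records
#'   whether the correction was applied).
#' @examples
#' barrier_strength(c(40, 60), c(40, 60))          # 1: no barrier
#' barrier_strength(c(99, 1), c(50, 50))           # 99
#' barrier_strength(c(100, 0), c(50, 50))          # 201, corrected
#' @export
barrier_strength <- function(test, control, correction = 0.5) {
  t <- .ear_counts(test, "test")
  ctl <- .ear_counts(control, "control")
  if (sum(t) == 0 && sum(ctl) == 0) stop("both ears are empty")
  if (!is.numeric(correction) || length(correction) != 1L || correction < 0) {
    stop("correction must be a single nonnegative number")
  }
  cells <- c(t, ctl)
  corrected <- any(cells == 0)
  if (corrected) cells <- cells + correction
  bs <- (cells[1] / cells[2]) / (cells[3] / cells[4])
  structure(bs, corrected = corrected)
}

#' Classify an ear's barrier status from a test/control comparison
#'
#' Applies the two-tailed exact test to the (yellow, purple) kernel counts of
#' a test ear against its control ear, and assigns the published two-tier
#' classification: `"strong"` when the test ear has a lower `tcb1`-sired
#' (purple) fraction and p < 0.0001, `"partial"` when 0.0001 <= p < 0.01 in
#' the same direction, otherwise `"none"`. Significance in the wrong
#' direction (more `tcb1` kernels on the test ear) never counts as a barrier.
#'
#' @param test,control Ear counts as in [barrier_strength()].
#' @param correction Zero-cell correction forwarded to [barrier_strength()].
#' @return A list of class `ear_classification`: `p_value`, `tier`,
#'   `barrier_strength`, `direction` (TRUE when the test ear has fewer
#'   `tcb1`-sired kernels).
#' @examples
#' classify_ear(c(200, 0), c(80, 120))  # strong
#' classify_ear(c(50, 50), c(50, 50))   # none
#' @export
classify_ear <- function(test, control, correction = 0.5) {
  t <- .ear_counts(test, "test")
  ctl <- .ear_counts(control, "control")
  if (sum(t) == 0 || sum(ctl) == 0) stop("cannot classify an empty ear")
  p <- exact_test_2x2(t[1], t[2], ctl[1], ctl[2])
  direction <- (t[2] / sum(t)) < (ctl[2] / sum(ctl))
  tier <- if (direction && p < 1e-4) {
    "strong"
  } else if (direction && p < 0.01) {
    "partial"
  } else {
    "none"
  }
  structure(
    list(p_value = p, tier = tier,
         barrier_strength = as.numeric(barrier_strength(t, ctl, correction)),
         direction = direction),
    class = "ear_classification"
  )
}

#' @export
print.ear_classification <- function(x, ...) {
  cat(sprintf("ear classification: tier = %s  (p = %.4g, barrier strength = %.3g)\n",
              x$tier, x$p_value, x$barrier_strength))
  invisible(x)
}

#' Cosegregation of a molecular marker with the barrier phenotype
#'
#' Counts concordant and discordant plants between marker presence and
#' barrier phenotype across recombinants, and computes the two-tailed exact
#' p-value on the marker x phenotype 2x2 table. Perfect cosegregation of the
#' candidate gene with barrier function across the 15 closest recombinants
#' (6 with both, 9 with neither) gives p = 1/5005.
#'
#' @param marker_present Logical vector: does the plant carry the candidate
#'   gene marker?
#' @param barrier_phenotype Logical vector of equal length: does the plant
#'   block incompatible pollen?
#' @return A list: `n_concordant`, `n_discordant`, `p_value`, `table` (the
#'   2x2 marker x phenotype matrix).
#' @examples
#' cosegregation(rep(c(TRUE, FALSE), c(6, 9)), rep(c(TRUE, FALSE), c(6, 9)))
#' @export
cosegregation <- function(marker_present, barrier_phenotype) {
  if (length(marker_present) != length(barrier_phenotype)) {
    stop("marker and phenotype vectors must have equal length")
  }
  stopifnot(is.logical(marker_present), is.logical(barrier_phenotype),
            !anyNA(marker_present), !anyNA(barrier_phenotype))
  a <- sum(marker_present & barrier_phenotype)
  b <- sum(marker_present & !barrier_phenotype)
  c <- sum(!marker_present & barrier_phenotype)
  d <- sum(!marker_present & !barrier_phenotype)
  tab <- matrix(c(a, c, b, d), nrow = 2L,
                dimnames = list(marker = c("present", "absent"),
                                barrier = c("present", "absent")))
  list(
    n_concordant = a + d,
    n_discordant = b + c,
    p_value = exact_test_2x2(a, b, c, d),
    table = tab
  )
}

#' Flag exceptional ears in an open-pollinated screen
#'
#' Each ear's sugary-kernel count is tested against the null barrier
#' expectation with a one-sided exact binomial tail
#' `P(X >= observed | null_fraction)`; an ear is flagged when its p-value
#' falls below a Bonferroni-corrected `alpha / n_ears`, giving strict
#' family-wise control over thousands of ears.
#'
#' @param ears Data.frame with columns `n_sugary` and `n_total` (as produced
#'   by [simulate_open_pollinated_screen()]).
#' @param null_fraction Null sugary fraction on barrier ears, typically
#'   `r/2`. Default 0.03.
#' @param alpha Family-wise error rate. Default 0.05.
#' @return The input data.frame with added columns `p_value` and `flagged`.
#' @export
flag_screen_outliers <- function(ears, null_fraction = 0.03, alpha = 0.05) {
  stopifnot(is.data.frame(ears),
            all(c("n_sugary", "n_total") %in% names(ears)))
  if (!is.numeric(null_fraction) || length(null_fraction) != 1L ||
      null_fraction <= 0 || null_fraction >= 1) {
    stop("null_fraction must be a single probability in (0, 1)")
  }
  stopifnot(alpha > 0, alpha <= 1)
  p <- stats::pbinom(ears$n_sugary - 1L, ears$n_total, null_fraction,
                     lower.tail = FALSE)
  ears$p_value <- p
  ears$flagged <- p < alpha / nrow(ears)
  ears
}
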