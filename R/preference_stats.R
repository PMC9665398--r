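# Descriptive and inferential battery for the categorical-preference and
# Likert-willingness sections: paired symmetry tests, t-tests, thresholded
# willingness shares and the three-mandate overlap partition.

test_result <- function(statistic, df, p_value, n) {
  structure(list(statistic = statistic, df = df, p_value = p_value, n = n),
            class = "dce_test")
}

#' @export
print.dce_test <- function(x, ...) {
  cat(sprintf("statistic = %.4f, df = %d, p = %.4g, n = %d\n",
              x$statistic, x$df, x$p_value, x$n))
  invisible(x)
}

#' Paired contingency table of preferences under two framings
#'
#' Cross-tabulates each participant's response under `frame1` (rows)
#' against `frame2` (columns) over the four preference categories.
#' Participants missing either frame are excluded (their count is reported
#' in a message).
#'
#' @param responses Preference table (`participant_id`, `frame`, `choice`).
#' @param frame1,frame2 Frame labels from [frames()].
#' @return A k x k integer matrix with category dimnames; attribute
#'   `n_excluded` gives the number of incomplete participants dropped.
#' @export
build_paired_table <- function(responses, frame1, frame2) {
  frame1 <- match.arg(frame1, frames())
  frame2 <- match.arg(frame2, frames())
  r1 <- responses[responses$frame == frame1, c("participant_id", "choice")]
  r2 <- responses[responses$frame == frame2, c("participant_id", "choice")]
  m <- merge(r1, r2, by = "participant_id", suffixes = c("_1", "_2"))
  n_excluded <- length(union(r1$participant_id, r2$participant_id)) - nrow(m)
  if (n_excluded > 0)
    message(sprintf("excluded %d participant(s) missing one frame", n_excluded))
  lev <- preference_choices()
  tab <- table(factor(m$choice_1, levels = lev), factor(m$choice_2, levels = lev))
  out <- unclass(as.matrix(tab))
  names(dimnames(out)) <- c(frame1, frame2)
  attr(out, "n_excluded") <- n_excluded
  out
}

#' McNemar-Bowker test of symmetry
#'
#' Tests whether a paired k x k table is symmetric: statistic
#' `sum over i < j of (n_ij - n_ji)^2 / (n_ij + n_ji)` restricted to
#' informative pairs (`n_ij + n_ji > 0`), with degrees of freedom equal to
#' the number of informative pairs and an upper-tail chi-square p-value.
#' On a 2 x 2 table this is the uncorrected McNemar statistic.
#'
#' @param table Square count matrix (k >= 2).
#' @return A `dce_test` (statistic, df, p_value, n = table total).
#' @export
bowker_test <- function(table) {
  tab <- as.matrix(table)
  k <- nrow(tab)
  if (k != ncol(tab) || k < 2) stop("`table` must be square, k >= 2", call. = FALSE)
  if (any(tab < 0)) stop("counts must be non-negative", call. = FALSE)
  stat <- 0
  df <- 0L
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      s <- tab[i, j] + tab[j, i]
      if (s > 0) {
        stat <- stat + (tab[i, j] - tab[j, i])^2 / s
        df <- df + 1L
      }
    }
  }
  if (df == 0L)
    stop("degenerate table: all off-diagonal pairs empty", call. = FALSE)
  test_result(stat, df, stats::pchisq(stat, df, lower.tail = FALSE), sum(tab))
}

#' Paired and two-sample t-tests with the study's df conventions
#'
#' `paired_t_test()` is the t-test on within-participant differences
#' (df = n - 1). `two_sample_t_test()` is the pooled-variance Student
#' t-test (df = n1 + n2 - 2), the convention that reproduces df = 530 for
#' samples of 186 and 346. Both report two-sided p-values. A degenerate
#' paired test with zero difference variance and zero mean difference
#' returns t = 0, p = 1 by convention.
#'
#' @param before,after Paired numeric vectors of equal length (>= 2).
#' @param x,y Independent samples (each length >= 2).
#' @return A `dce_test`.
#' @export
paired_t_test <- function(before, after) {
  stopifnot(length(before) == length(after), length(before) >= 2)
  d <- before - after
  n <- length(d)
  if (stats::sd(d) == 0) {
    if (mean(d) == 0) return(test_result(0, n - 1L, 1, n))
    stop("constant non-zero differences: t undefined", call. = FALSE)
  }
  tt <- stats::t.test(before, after, paired = TRUE)
  test_result(unname(tt$statistic), as.integer(unname(tt$parameter)),
              tt$p.value, n)
}

#' @rdname paired_t_test
#' @export
two_sample_t_test <- function(x, y) {
  stopifnot(length(x) >= 2, length(y) >= 2)
  tt <- stats::t.test(x, y, var.equal = TRUE)
  test_result(unname(tt$statistic), as.integer(unname(tt$parameter)),
              tt$p.value, length(x) + length(y))
}

#' Willingness-to-purchase summary for one condition
#'
#' Summarises 1-7 Likert responses: mean, standard error (sd / sqrt(n)),
#' median, the percentage answering "likely" (response strictly greater
#' than 4) and "neither likely nor unlikely" (response exactly 4).
#' Percentages are reported to one decimal place, half-up.
#'
#' @param likert Likert table (`condition`, `response` columns).
#' @param condition Condition label from [conditions()].
#' @return List with `mean`, `se`, `median`, `share_likely`,
#'   `share_neither` (shares in percent) and `n`.
#' @export
willingness_summary <- function(likert, condition) {
  condition <- match.arg(condition, conditions())
  r <- likert$response[likert$condition == condition]
  if (length(r) == 0L) stop("no responses for condition ", condition, call. = FALSE)
  if (any(r < 1 | r > 7)) stop("responses must lie in 1..7", call. = FALSE)
  n <- length(r)
  round_half_up <- function(x, digits = 1) floor(x * 10^digits + 0.5) / 10^digits
  list(mean = mean(r),
       se = stats::sd(r) / sqrt(n),
       median = stats::median(r),
       share_likely = round_half_up(100 * mean(r > 4)),
       share_neither = round_half_up(100 * mean(r == 4)),
       n = n)
}

#' Overlap partition of willingness across the three mandates
#'
#' Classifies every participant with all three mandate responses as likely
#' (response > 4) or not under each mandate, yielding the 2^3 = 8 cells of
#' the three-set overlap diagram (including the "none" cell of participants
#' unwilling under every mandate). Cells are exhaustive and disjoint;
#' shares are percentages of complete participants.
#'
#' @param likert Likert table with the three `MANDATE_*` conditions.
#' @return Data frame with logical columns `most`, `ped`, `occ`, the cell
#'   `count` and `share` (exact percent of complete participants); attribute
#'   `n_excluded` counts participants missing a mandate response.
#' @export
overlap_partition <- function(likert) {
  mand <- c("MANDATE_MOST", "MANDATE_PED", "MANDATE_OCC")
  sub <- likert[likert$condition %in% mand, , drop = FALSE]
  wide <- stats::reshape(sub[, c("participant_id", "condition", "response")],
                         idvar = "participant_id", timevar = "condition",
                         direction = "wide")
  cols <- paste0("response.", mand)
  complete <- stats::complete.cases(wide[, cols])
  n_excluded <- sum(!complete)
  if (n_excluded > 0)
    message(sprintf("excluded %d participant(s) missing a mandate response",
                    n_excluded))
  wide <- wide[complete, , drop = FALSE]
  n <- nrow(wide)
  if (n == 0L) stop("no complete participants", call. = FALSE)
  likely <- wide[, cols] > 4
  cells <- expand.grid(most = c(TRUE, FALSE), ped = c(TRUE, FALSE),
                       occ = c(TRUE, FALSE))
  key <- paste(likely[, 1], likely[, 2], likely[, 3])
  cellkey <- paste(cells$most, cells$ped, cells$occ)
  count <- vapply(cellkey, function(k) sum(key == k), integer(1))
  # shares stay exact so the partition identity (sum = 100) holds; round only
  # for presentation
  out <- data.frame(cells, count = unname(count),
                    share = 100 * unname(count) / n)
  attr(out, "n_complete") <- n
  attr(out, "n_excluded") <- n_excluded
  out
}

#' Run the full preference and willingness test battery
#'
#' Computes the symmetry tests of each family framing against the unframed
#' question and of the moral question against the unframed question, the
#' paired t-tests of baseline willingness against each mandate condition,
#' and the per-condition willingness summaries.
#'
#' @param preferences Preference table.
#' @param likert Likert table.
#' @return Data frame with one row per test: `test`, `statistic`, `df`,
#'   `p_value`, `n`.
#' @export
preference_battery <- function(preferences, likert) {
  rows <- list()
  pairs <- list(c("UNFRAMED", "FAMILY_PASSENGER"),
                c("UNFRAMED", "FAMILY_PEDESTRIAN"),
                c("UNFRAMED", "MORAL"))
  for (p in pairs) {
    tab <- build_paired_table(preferences, p[1], p[2])
    bt <- bowker_test(tab)
    rows[[length(rows) + 1]] <- data.frame(
      test = sprintf("bowker_%s_vs_%s", tolower(p[1]), tolower(p[2])),
      statistic = bt$statistic, df = bt$df, p_value = bt$p_value, n = bt$n)
  }
  wide <- stats::reshape(likert[, c("participant_id", "condition", "response")],
                         idvar = "participant_id", timevar = "condition",
                         direction = "wide")
  for (cond in c("MANDATE_MOST", "MANDATE_PED", "MANDATE_OCC")) {
    b <- wide$response.BASELINE
    a <- wide[[paste0("response.", cond)]]
    ok <- stats::complete.cases(b, a)
    tt <- paired_t_test(b[ok], a[ok])
    rows[[length(rows) + 1]] <- data.frame(
      test = sprintf("paired_t_baseline_vs_%s", tolower(cond)),
      statistic = tt$statistic, df = tt$df, p_value = tt$p_value, n = tt$n)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
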