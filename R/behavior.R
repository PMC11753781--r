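#' Conditioned-place-preference time percentage
#'
#' Percentage of (non-middle) session time spent in the reward-paired
#' compartment: `100 * t_paired / (total - t_middle)`, i.e.
#' `100 * t_paired / (t_paired + t_other)`. Time in the middle area is
#' excluded from the denominator, so the result is invariant to how long
#' the animal sat in the middle.
#'
#' @param t_paired,t_other,t_middle non-negative times (seconds) in the
#'   paired compartment, the other compartment and the middle area.
#' @return Percentage in `[0, 100]`.
#' @examples
#' cpp_percentage(600, 1000, 200)  # 37.5
#' @export
cpp_percentage <- function(t_paired, t_other, t_middle = 0) {
  if (any(c(t_paired, t_other, t_middle) < 0))
    stop("times must be non-negative")
  denom <- t_paired + t_other
  if (any(denom <= 0))
    stop("animal never left the middle area: preference undefined")
  100 * t_paired / denom
}

#' Conditioned-place-preference score
#'
#' Percent change of the paired-compartment time percentage from the
#' pre-test days to the test day:
#' `100 * (pct_test - pct_pre) / pct_pre`. A score above zero indicates a
#' developed place preference. When several pre-test days exist, pass their
#' mean percentage as `pct_pre`.
#'
#' @param pct_test percentage on the test day.
#' @param pct_pre percentage on the pre-test day(s), > 0.
#' @return The CPP score.
#' @examples
#' cpp_score(50, 40)   # 25
#' cpp_score(40, 50)   # -20
#' @export
cpp_score <- function(pct_test, pct_pre) {
  if (any(pct_pre <= 0)) stop("pre-test percentage must be > 0")
  100 * (pct_test - pct_pre) / pct_pre
}

#' CPP scores from a session table
#'
#' Computes per-animal CPP scores from a long table with columns
#' `animal, phase` (`"pre"`/`"test"`), `t_paired, t_other, t_middle`.
#' The pre-test percentage is the mean over all pre-test days.
#'
#' @param cpp_table data frame as produced by [generate_behavior_tables()].
#' @return A data frame with columns `animal, pct_pre, pct_test, score`.
#' @export
cpp_score_table <- function(cpp_table) {
  need <- c("animal", "phase", "t_paired", "t_other", "t_middle")
  if (!all(need %in% names(cpp_table)))
    stop("cpp table needs columns ", paste(need, collapse = ", "))
  pct <- cpp_percentage(cpp_table$t_paired, cpp_table$t_other,
                        cpp_table$t_middle)
  do.call(rbind, lapply(split(seq_len(nrow(cpp_table)), cpp_table$animal),
    function(ix) {
      pre <- mean(pct[ix][cpp_table$phase[ix] == "pre"])
      test <- mean(pct[ix][cpp_table$phase[ix] == "test"])
      data.frame(animal = cpp_table$animal[ix][1], pct_pre = pre,
                 pct_test = test, score = cpp_score(test, pre))
    }))
}

#' Two-bottle preference percentage
#'
#' Solution consumption as a percentage of total drinking:
#' `100 * solution / (solution + water)`. Values above 50% indicate a
#' preference for the solution.
#'
#' @param solution_intake,water_intake non-negative intakes (g or ml);
#'   their sum must be positive.
#' @return Percentage in `[0, 100]`.
#' @export
preference_percentage <- function(solution_intake, water_intake) {
  if (any(c(solution_intake, water_intake) < 0))
    stop("intakes must be non-negative")
  total <- solution_intake + water_intake
  if (any(total <= 0)) stop("zero total intake: preference undefined")
  100 * solution_intake / total
}

#' Group preference test against 50%
#'
#' One-sample two-tailed t-test of per-animal preference percentages
#' against the indifference point of 50%.
#'
#' @param percentages per-animal preference percentages, n >= 2.
#' @return A list with `mean`, `sem`, `n`, `t`, `p`, `df`.
#' @export
preference_test <- function(percentages) {
  x <- as.numeric(percentages)
  if (length(x) < 2L) stop("need at least two animals")
  r <- population_response(x - 50)
  list(mean = r$mean + 50, sem = r$sem, n = r$n, t = r$t, p = r$p,
       df = r$df)
}

#' Locomotor activity AUC
#'
#' Trapezoidal integral of activity counts over a time window (e.g. the
#' pre- or post-injection period of an ICV experiment). Bin times are bin
#' midpoints in minutes; the window selects bins by midpoint, half-open
#' `[start, end]` inclusive of both endpoints when they coincide with bin
#' times.
#'
#' @param bin_times_min bin times, minutes, strictly increasing.
#' @param counts activity counts per bin.
#' @param window `(start, end)` minutes, inside the recording.
#' @return AUC in count-minutes.
#' @examples
#' locomotor_auc(0:30, rep(10, 31), c(0, 30))  # 300
#' @export
locomotor_auc <- function(bin_times_min, counts, window) {
  bin_times_min <- as.numeric(bin_times_min)
  counts <- as.numeric(counts)
  if (length(bin_times_min) != length(counts))
    stop("bin times and counts must have equal length")
  if (any(diff(bin_times_min) <= 0))
    stop("bin times must be strictly increasing")
  if (length(window) != 2L || window[1] >= window[2])
    stop("window must be an ordered (start, end) pair")
  if (window[1] < min(bin_times_min) - 1e-9 ||
      window[2] > max(bin_times_min) + 1e-9)
    stop("window must lie inside the recording")
  sel <- bin_times_min >= window[1] - 1e-9 & bin_times_min <= window[2] + 1e-9
  t <- bin_times_min[sel]; y <- counts[sel]
  if (length(t) < 2L) stop("window contains fewer than two bins")
  sum(diff(t) * (y[-1] + y[-length(y)]) / 2)
}
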