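#' UVA exposure schedule
#'
#' Irradiance with optional measurement tolerance, daily exposure duration
#' and number of exposure days.
#'
#' @param irradiance_mw_cm2 irradiance in mW/cm^2 (> 0).
#' @param hours_per_day daily exposure in hours (>= 0).
#' @param days number of exposure days (integer >= 1).
#' @param tolerance_mw_cm2 half-width of the irradiance uncertainty
#'   (mW/cm^2), carried through as a dose interval; 0 disables.
#' @return A list of class `exposure_schedule`.
#' @export
exposure_schedule <- function(irradiance_mw_cm2, hours_per_day, days,
                              tolerance_mw_cm2 = 0) {
  if (irradiance_mw_cm2 <= 0) stop("irradiance must be > 0")
  if (hours_per_day < 0) stop("hours_per_day must be >= 0")
  if (days < 1) stop("days must be >= 1")
  if (tolerance_mw_cm2 < 0) stop("tolerance must be >= 0")
  structure(list(irradiance_mw_cm2 = irradiance_mw_cm2,
                 hours_per_day = hours_per_day,
                 days = as.integer(days),
                 tolerance_mw_cm2 = tolerance_mw_cm2),
            class = "exposure_schedule")
}

#' Radiant exposure (dose) from an exposure schedule
#'
#' Daily dose in J/cm^2 is irradiance (mW/cm^2) times seconds of exposure
#' divided by 1000; total dose is daily times days. Exact arithmetic, no
#' rounding. An irradiance tolerance widens into a min/max dose interval
#' (reported, not propagated into statistics).
#'
#' @param schedule an [exposure_schedule], or irradiance in mW/cm^2 when the
#'   remaining arguments are given directly.
#' @param hours_per_day,days,tolerance_mw_cm2 used when `schedule` is a bare
#'   irradiance value.
#' @return A list of class `dose_result`: `daily_j_cm2`, `total_j_cm2`, and
#'   `interval_total_j_cm2` (length-2, only when a tolerance is present).
#' @examples
#' radiant_exposure(0.45, hours_per_day = 2, days = 7) # 3.24 J/cm2/day, 22.68 total
#' @export
radiant_exposure <- function(schedule, hours_per_day = NULL, days = NULL,
                             tolerance_mw_cm2 = 0) {
  if (!inherits(schedule, "exposure_schedule")) {
    if (is.null(hours_per_day) || is.null(days))
      stop("give an exposure_schedule or (irradiance, hours_per_day, days)")
    schedule <- exposure_schedule(schedule, hours_per_day, days, tolerance_mw_cm2)
  }
  secs <- schedule$hours_per_day * 3600
  daily <- schedule$irradiance_mw_cm2 * secs / 1000
  total <- daily * schedule$days
  out <- list(daily_j_cm2 = daily, total_j_cm2 = total)
  if (schedule$tolerance_mw_cm2 > 0) {
    lohi <- (schedule$irradiance_mw_cm2 + c(-1, 1) * schedule$tolerance_mw_cm2) *
      secs / 1000 * schedule$days
    out$interval_total_j_cm2 <- lohi
  }
  structure(out, class = "dose_result")
}

#' @export
print.dose_result <- function(x, ...) {
  cat(sprintf("<dose_result> %.4g J/cm2 per day, %.4g J/cm2 total",
              x$daily_j_cm2, x$total_j_cm2))
  if (!is.null(x$interval_total_j_cm2))
    cat(sprintf(" (interval %.4g-%.4g)", x$interval_total_j_cm2[1L],
                x$interval_total_j_cm2[2L]))
  cat("\n")
  invisible(x)
}

#' Normalize measurements to the control-group mean
#'
#' Each value is divided by the mean of the control group, so the control
#' group normalizes to mean 1 and treatment values read as fold-change
#' against control. Scale-invariant end-to-end: multiplying all inputs by a
#' constant leaves the normalized values unchanged.
#'
#' @param values per-sample scalars to normalize.
#' @param control_values per-sample control scalars (non-empty, mean > 0).
#' @return Normalized `values`.
#' @export
normalize_to_control <- function(values, control_values) {
  if (length(control_values) == 0L) stop("control set is empty")
  m <- mean(control_values)
  if (!is.finite(m) || m <= 0) stop("control mean must be > 0")
  values / m
}

#' Two-group or multi-group comparison
#'
#' Two groups are compared by an unpaired two-tailed t-test (pooled variance
#' by default, Welch optional); more than two groups by one-way ANOVA
#' followed by Tukey's HSD pairwise tests. Significance is flagged at 0.05
#' (`*`) and 0.01 (`**`).
#'
#' @param a numeric vector (first group), or a named list of >= 3 groups for
#'   `method = "anova_tukey"`.
#' @param b numeric vector (second group) for `method = "t_test"`.
#' @param method `"t_test"` or `"anova_tukey"`.
#' @param var_equal pooled-variance t-test when `TRUE` (default); Welch
#'   otherwise.
#' @return A list of class `group_comparison`: `test_name`, `statistic`,
#'   `p_value`, `significance`, and for ANOVA a `pairwise` data frame of
#'   Tukey-adjusted comparisons.
#' @export
compare_groups <- function(a, b = NULL, method = c("t_test", "anova_tukey"),
                           var_equal = TRUE) {
  method <- match.arg(method)
  star <- function(p) if (p < 0.01) "**" else if (p < 0.05) "*" else "ns"
  if (method == "t_test") {
    if (length(a) < 2L || length(b) < 2L) stop("each group needs n >= 2")
    if (sd(a) == 0 && sd(b) == 0) {
      if (identical(mean(a), mean(b)))
        return(structure(list(test_name = if (var_equal) "t (pooled)" else "t (Welch)",
                              statistic = 0, p_value = 1, significance = "ns"),
                         class = "group_comparison"))
      stop("zero variance in both groups with different means: t undefined")
    }
    tt <- t.test(a, b, var.equal = var_equal)
    structure(list(test_name = if (var_equal) "t (pooled)" else "t (Welch)",
                   statistic = unname(tt$statistic), p_value = tt$p.value,
                   significance = star(tt$p.value)),
              class = "group_comparison")
  } else {
    if (!is.list(a) || length(a) < 3L)
      stop("anova_tukey needs a named list of >= 3 groups")
    if (any(lengths(a) < 2L)) stop("each group needs n >= 2")
    if (is.null(names(a))) names(a) <- paste0("g", seq_along(a))
    df <- data.frame(value = unlist(a),
                     group = factor(rep(names(a), lengths(a))))
    fit <- aov(value ~ group, data = df)
    sm <- summary(fit)[[1L]]
    p <- sm[["Pr(>F)"]][1L]
    tk <- TukeyHSD(fit)$group
    pairwise <- data.frame(comparison = rownames(tk),
                           diff = tk[, "diff"], p_adj = tk[, "p adj"],
                           significance = vapply(tk[, "p adj"], star, character(1)),
                           row.names = NULL)
    structure(list(test_name = "one-way ANOVA + Tukey HSD",
                   statistic = sm[["F value"]][1L], p_value = p,
                   significance = star(p), pairwise = pairwise),
              class = "group_comparison")
  }
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s: statistic %.4g, p = %.4g [%s]\n",
              x$test_name, x$statistic, x$p_value, x$significance))
  if (!is.null(x$pairwise)) {
    cat("  pairwise (Tukey-adjusted):\n")
    for (i in seq_len(nrow(x$pairwise)))
      cat(sprintf("    %s: diff %.4g, p = %.4g [%s]\n",
                  x$pairwise$comparison[i], x$pairwise$diff[i],
                  x$pairwise$p_adj[i], x$pairwise$significance[i]))
  }
  invisible(x)
}
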