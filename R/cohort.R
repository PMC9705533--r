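#' Median and interquartile range
#'
#' Quantiles by the linear-interpolation convention (R's default type 7),
#' the most common choice; for odd `n` with distinct values this gives the
#' familiar exact quartiles (e.g. `1:5` -> 3 (2-4)).
#'
#' @param values numeric vector, `NA`s removed; at least one value must
#'   remain.
#' @return Named numeric vector `c(median, q1, q3)`.
#' @export
median_iqr <- function(values) {
  values <- values[!is.na(values)]
  if (!length(values)) stop("no values: cannot form median/IQR", call. = FALSE)
  q <- stats::quantile(values, c(0.5, 0.25, 0.75), names = FALSE, type = 7)
  c(median = q[1], q1 = q[2], q3 = q[3])
}

#' Mann-Whitney U test (exact or asymptotic, two-sided)
#'
#' `U` is the Mann-Whitney statistic of the first group (rank sum minus its
#' minimum); `U_a + U_b = n_a * n_b` always. Exact mode evaluates the
#' rank-permutation null distribution (valid only without ties; it is the
#' mode of record for small samples, `min(n) <= 8`); asymptotic mode uses
#' the normal approximation with tie correction and continuity correction.
#' Two-sided p values throughout: exact p is `min(1, 2 * min(lower tail,
#' upper tail))`.
#'
#' @param group_a,group_b numeric samples, both non-empty (`NA`s removed).
#' @param mode `"auto"` (exact when tie-free, asymptotic otherwise),
#'   `"exact"` (errors on ties) or `"asymptotic"`.
#' @return List with `U` (for `group_a`), `p` (two-sided), `mode_used`,
#'   `n_a`, `n_b`.
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6), mode = "exact")  # U = 0, p = 0.1
#' @export
mann_whitney_u <- function(group_a, group_b,
                           mode = c("auto", "exact", "asymptotic")) {
  mode <- match.arg(mode)
  a <- group_a[!is.na(group_a)]; b <- group_b[!is.na(group_b)]
  if (!length(a) || !length(b))
    stop("both groups need at least one observation", call. = FALSE)
  m <- length(a); n <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  U <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  ties <- any(duplicated(pooled))
  if (mode == "exact" && ties)
    stop("exact mode requires tie-free data; use asymptotic mode", call. = FALSE)
  use_exact <- switch(mode, exact = TRUE, asymptotic = FALSE, auto = !ties)
  if (use_exact) {
    # rank-permutation null via the exact U distribution (no ties)
    lower <- stats::pwilcox(U, m, n)
    upper <- 1 - stats::pwilcox(U - 1, m, n)
    p <- min(1, 2 * min(lower, upper))
    mode_used <- "exact"
  } else {
    mu <- m * n / 2
    N <- m + n
    tie_tab <- table(pooled)
    tie_term <- sum(tie_tab^3 - tie_tab) / (N * (N - 1))
    sigma2 <- m * n / 12 * ((N + 1) - tie_term)
    z <- max(0, abs(U - mu) - 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(z, lower.tail = FALSE))
    mode_used <- "asymptotic"
  }
  list(U = U, p = p, mode_used = mode_used, n_a = m, n_b = n)
}

#' Assemble a tidy cohort table
#'
#' One row per subject-finger-metric measurement (tidy layout, the CSV
#' interchange format of the pipeline). Groups are `HC` (healthy control)
#' and `SSc`; SSc subjects may carry a subgroup, `SSc_isch` (history of
#' severe digital ischaemia) or `SSc_no_isch`.
#'
#' @param subject_id character/factor subject identifiers.
#' @param group `"HC"` or `"SSc"` per row.
#' @param metric metric name per row (e.g. `"vascular_volume_mm3"`,
#'   `"baseline_so2"`).
#' @param value numeric measurement (`NA` = missing finger).
#' @param finger finger index 1-8, or `NA` for subject-level metrics.
#' @param subgroup `"none"`, `"SSc_isch"` or `"SSc_no_isch"`; `"none"` is
#'   required for HC subjects.
#' @return Validated data.frame of class `cohort_records`.
#' @export
cohort_records <- function(subject_id, group, metric, value,
                           finger = NA_integer_, subgroup = "none") {
  d <- data.frame(subject_id = as.character(subject_id),
                  group = as.character(group),
                  subgroup = as.character(subgroup),
                  finger = as.integer(finger),
                  metric = as.character(metric),
                  value = as.numeric(value),
                  stringsAsFactors = FALSE)
  if (!all(d$group %in% c("HC", "SSc")))
    stop("group must be 'HC' or 'SSc'", call. = FALSE)
  if (!all(d$subgroup %in% c("none", "SSc_isch", "SSc_no_isch")))
    stop("subgroup must be none/SSc_isch/SSc_no_isch", call. = FALSE)
  if (any(d$group == "HC" & d$subgroup != "none"))
    stop("HC subjects cannot carry an SSc subgroup", call. = FALSE)
  if (any(!is.na(d$finger) & !(d$finger %in% 1:8)))
    stop("finger index must be 1..8 (or NA)", call. = FALSE)
  class(d) <- c("cohort_records", "data.frame")
  d
}

#' Group-comparison table (median/IQR + Mann-Whitney U)
#'
#' Reproduces the layout of the study's results tables for one metric:
#' a healthy-control vs SSc row with per-group n, median, IQR and a
#' two-sided Mann-Whitney U test, plus descriptive-only rows for the SSc
#' ischaemia-history subgroups (no formal test — subgroup numbers are too
#' small, so test fields are `NA` by design). Data are compared either at
#' finger level (each finger one observation) or as the mean of the eight
#' fingers per subject ([mean_over_fingers()]).
#'
#' @param records a [cohort_records()] table.
#' @param metric metric name to tabulate; an unknown name errors listing
#'   the available metrics.
#' @param level `"mean_of_8"` (default) or `"finger"`.
#' @param mode Mann-Whitney mode flag, recorded in the output.
#' @return data.frame of class `group_comparison` with columns
#'   `metric, comparison, group, n, median, q1, q3, U, p, test_mode,
#'   compared_at`.
#' @export
build_comparison_table <- function(records, metric,
                                   level = c("mean_of_8", "finger"),
                                   mode = c("auto", "exact", "asymptotic")) {
  stopifnot(inherits(records, "cohort_records"))
  level <- match.arg(level); mode <- match.arg(mode)
  avail <- unique(records$metric)
  if (!metric %in% avail)
    stop(sprintf("unknown metric '%s'; available: %s", metric,
                 paste(avail, collapse = ", ")), call. = FALSE)
  d <- records[records$metric == metric, ]
  values_of <- function(sel) {
    dd <- d[sel, ]
    if (!nrow(dd)) return(numeric(0))
    if (level == "finger" || all(is.na(dd$finger))) {
      dd$value[!is.na(dd$value)]
    } else {
      unlist(lapply(split(dd, dd$subject_id), function(s)
        suppressWarnings(tryCatch(mean_over_fingers(s$value),
                                  error = function(e) NA_real_))))
    }
  }
  hc  <- values_of(d$group == "HC")
  ssc <- values_of(d$group == "SSc")
  if (!length(hc) || !length(ssc))
    stop("need at least one observation per group (HC and SSc)", call. = FALSE)
  test <- mann_whitney_u(hc, ssc, mode = mode)
  row <- function(comparison, group, v, U = NA_real_, p = NA_real_,
                  tmode = NA_character_) {
    if (!length(v))
      return(data.frame(metric = metric, comparison = comparison,
                        group = group, n = 0L, median = NA_real_,
                        q1 = NA_real_, q3 = NA_real_, U = U, p = p,
                        test_mode = tmode, compared_at = level,
                        stringsAsFactors = FALSE))
    mq <- median_iqr(v)
    data.frame(metric = metric, comparison = comparison, group = group,
               n = length(v), median = mq["median"], q1 = mq["q1"],
               q3 = mq["q3"], U = U, p = p, test_mode = tmode,
               compared_at = level, stringsAsFactors = FALSE)
  }
  out <- rbind(
    row("HC_vs_SSc", "HC", hc, test$U, test$p, test$mode_used),
    row("HC_vs_SSc", "SSc", ssc, test$U, test$p, test$mode_used),
    row("SSc_subgroups", "SSc_isch",
        values_of(d$subgroup == "SSc_isch")),
    row("SSc_subgroups", "SSc_no_isch",
        values_of(d$subgroup == "SSc_no_isch")))
  rownames(out) <- NULL
  class(out) <- c("group_comparison", "data.frame")
  out
}

#' Format a comparison table in the printed-table style
#'
#' Volumes rounded to 1 decimal place, sO2 metrics to 3, in
#' "median (q1-q3)" form, with the significance footnote. Purely cosmetic;
#' machine output keeps full precision.
#'
#' @param tab a [build_comparison_table()] result.
#' @return Character vector of formatted lines.
#' @export
format_comparison_table <- function(tab) {
  stopifnot(inherits(tab, "group_comparison"))
  digits <- if (grepl("volume", tab$metric[1])) 1L else 3L
  fmt <- function(x) formatC(x, digits = digits, format = "f")
  lines <- sprintf("%-12s %-12s n=%-3d %s (%s-%s)%s",
                   tab$comparison, tab$group, tab$n,
                   fmt(tab$median), fmt(tab$q1), fmt(tab$q3),
                   ifelse(is.na(tab$p), "",
                          sprintf("  p=%s%s", format.pval(tab$p, digits = 2),
                                  ifelse(tab$p < 0.05, "*", ""))))
  c(sprintf("metric: %s (%s)", tab$metric[1], tab$compared_at[1]), lines,
    "*p < 0.05 is significant; subgroup rows are descriptive only")
}
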