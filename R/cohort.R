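# Batch application of the LV surface-area model to sex x age-group
# reference tables: area tables, male/female percentage differences,
# reference comparison, and the small-sample area-volume correlation.

.aggregate_labels <- "total"

.validate_cohort <- function(records) {
  if (!is.data.frame(records) || nrow(records) == 0L)
    stop("cohort records must be a non-empty data frame", call. = FALSE)
  needed <- c("sex", "age_group", "D_d", "V_dn")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols))
    stop("cohort records lack column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (!all(records$sex %in% c("female", "male")))
    stop("'sex' must be \"female\" or \"male\"", call. = FALSE)
  if (any(!is.finite(records$D_d) | records$D_d <= 0))
    stop("'D_d' must be positive", call. = FALSE)
  if (any(!is.finite(records$V_dn) | records$V_dn <= 0))
    stop("'V_dn' must be positive", call. = FALSE)
  key <- paste(records$sex, records$age_group)
  if (anyDuplicated(key))
    stop("duplicate (sex, age_group) combination: ",
         paste(unique(key[duplicated(key)]), collapse = "; "), call. = FALSE)
  invisible(records)
}

#' Percentage difference between male and female LV areas
#'
#' The unsigned percentage excess of the male over the female area,
#' \eqn{100\,|A_{men} - A_{women}| / A_{women}}. Because the area scales as
#' \eqn{D^2} at fixed axis ratio, this equals
#' \eqn{100\,((D_{men}/D_{women})^2 - 1)} when \eqn{D_{men} \ge D_{women}}
#' and is independent of `delta`.
#'
#' @param area_men,area_women areas (cm^2), positive; recycled.
#' @return Percentage (on the 0-100 scale).
#' @export
#' @examples
#' percentage_difference(145.40, 128.14)   # 13.47
percentage_difference <- function(area_men, area_women) {
  if (any(!is.finite(area_men) | area_men <= 0))
    stop("'area_men' must be positive", call. = FALSE)
  if (any(!is.finite(area_women) | area_women <= 0))
    stop("'area_women' must be positive", call. = FALSE)
  100 * abs(area_men - area_women) / area_women
}

#' Signed percentage shortfall relative to a reference area
#'
#' \eqn{100\,(A_{ref} - A)/A_{ref}}: positive when the computed area falls
#' below the reference. The default reference, 151 cm^2, is a published
#' nuclear-imaging estimate of the mean LV surface area and can be
#' overridden (see [lv_config()]).
#'
#' @param area computed area (cm^2).
#' @param reference reference area (cm^2), positive.
#' @return Signed percentage.
#' @export
#' @examples
#' compare_to_reference(145.40, 151)   # 3.71
compare_to_reference <- function(area, reference = lv_config()$reference_area) {
  if (any(!is.finite(reference) | reference <= 0))
    stop("'reference' must be positive", call. = FALSE)
  100 * (reference - area) / reference
}

#' Per-delta LV surface-area table for a cohort
#'
#' One row per cohort record and axis-ratio value: the TPS axes
#' (`a`, `abs_sigma`, `c`, `L`), the surface area `area`, and — where both
#' sexes are present for an age group — the male-vs-female percentage
#' difference `pct_diff` (attached to both rows of the pair, `NA`
#' otherwise).
#'
#' @param records data frame with columns `sex` (`"female"`/`"male"`),
#'   `age_group` (character label), `D_d` (end-diastolic short-axis
#'   diameter, cm) and `V_dn` (normalized end-diastolic volume, mL/m^2);
#'   see [builtin_reference_cohort()] for the bundled reference table.
#' @param deltas numeric vector of axis-ratio values in `(0, 1)`.
#' @return Data frame with columns `delta`, `sex`, `age_group`, `D_d`,
#'   `V_dn`, `a`, `abs_sigma`, `c`, `L`, `area`, `pct_diff`.
#' @seealso [lv_area_model()] for the full analysis.
#' @export
#' @examples
#' tab <- build_area_table(builtin_reference_cohort(), c(0.45, 0.50, 0.62))
#' subset(tab, age_group == "total" & delta == 0.45)
build_area_table <- function(records, deltas) {
  .validate_cohort(records)
  deltas <- as.numeric(deltas)
  if (length(deltas) == 0L || any(!is.finite(deltas) | deltas <= 0 | deltas >= 1))
    stop("'deltas' must be values in (0, 1)", call. = FALSE)
  out <- do.call(rbind, lapply(deltas, function(d) {
    ax <- suppressWarnings(lv_axes(records$D_d, d))
    data.frame(delta = d,
               sex = records$sex,
               age_group = records$age_group,
               D_d = records$D_d,
               V_dn = records$V_dn,
               a = ax$a,
               abs_sigma = ax$abs_sigma,
               c = ax$c,
               L = ax$L,
               area = tps_area(ax$a, ax$c, ax$sigma))
  }))
  out$pct_diff <- NA_real_
  for (d in deltas) for (g in unique(out$age_group)) {
    i_m <- which(out$delta == d & out$age_group == g & out$sex == "male")
    i_f <- which(out$delta == d & out$age_group == g & out$sex == "female")
    if (length(i_m) == 1L && length(i_f) == 1L)
      out$pct_diff[c(i_m, i_f)] <-
        percentage_difference(out$area[i_m], out$area[i_f])
  }
  rownames(out) <- NULL
  out
}

#' Pearson correlation with small-sample Student-t significance
#'
#' Pearson's `r` between two samples, with the significance of the
#' correlation assessed by \eqn{t = r\sqrt{n-2}/\sqrt{1-r^2}} on `n - 2`
#' degrees of freedom, and the least-squares line of `y` on `x`. Intended
#' for the very small samples typical of age-group summaries (`n >= 3`).
#'
#' @param x,y numeric vectors of equal length `n >= 3`, each with non-zero
#'   variance.
#' @param tails `2` (default) for a two-tailed p-value, `1` for the
#'   one-tailed probability of a correlation at least as large as observed.
#' @return Object of class `"lv_correlation"`: a list with `r`,
#'   `r_squared`, `t_stat`, `df`, `p_value`, `slope`, `intercept`, `n`,
#'   `tails`.
#' @export
#' @examples
#' with(subset(build_area_table(builtin_reference_cohort(), 0.45),
#'             sex == "male" & age_group != "total"),
#'      pearson_with_significance(V_dn, area))
pearson_with_significance <- function(x, y, tails = 2) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y))
    stop("'x' and 'y' must have equal length", call. = FALSE)
  n <- length(x)
  if (n < 3L)
    stop("need at least 3 observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in 'x' or 'y'", call. = FALSE)
  if (!tails %in% c(1, 2))
    stop("'tails' must be 1 or 2", call. = FALSE)
  r <- stats::cor(x, y)
  df <- n - 2L
  t_stat <- r * sqrt(df) / sqrt(max(1 - r^2, 0))
  p <- if (tails == 2) 2 * stats::pt(-abs(t_stat), df)
       else stats::pt(t_stat, df, lower.tail = FALSE)
  fit <- stats::lm.fit(cbind(1, x), y)
  res <- list(r = r, r_squared = r^2, t_stat = t_stat, df = df,
              p_value = min(p, 1), slope = unname(fit$coefficients[2L]),
              intercept = unname(fit$coefficients[1L]), n = n, tails = tails)
  class(res) <- "lv_correlation"
  res
}

#' @export
print.lv_correlation <- function(x, digits = 4, ...) {
  cat(sprintf("Pearson correlation (n = %d, df = %d)\n", x$n, x$df))
  cat(sprintf("  r = %.*f, R^2 = %.*f\n", digits, x$r, digits, x$r_squared))
  cat(sprintf("  t = %.*f, %s p = %.*f\n", digits, x$t_stat,
              if (x$tails == 2) "two-tailed" else "one-tailed",
              digits, x$p_value))
  cat(sprintf("  regression: y = %.*f + %.*f x\n",
              digits, x$intercept, digits, x$slope))
  invisible(x)
}

#' Check delta-invariance of percentage differences and correlations
#'
#' Because the area scales as \eqn{D^2} at fixed axis ratio, both the
#' male/female percentage differences and the Pearson correlation of area
#' with normalized volume are mathematically independent of `delta`. This
#' verifies both numerically across the supplied `deltas`.
#'
#' @inheritParams build_area_table
#' @param exclude age-group labels excluded from the correlation (aggregate
#'   rows; default `"total"`).
#' @return List with `pass` (logical), `pct_diff_max_rel` (largest relative
#'   spread of a percentage difference across deltas), `r_max_diff`
#'   (largest absolute spread of a per-sex correlation across deltas), and
#'   `pct_diff` (named per-age-group values at the first delta).
#' @export
delta_invariance_check <- function(records, deltas,
                                   exclude = .aggregate_labels) {
  if (length(deltas) < 2L)
    return(list(pass = TRUE, pct_diff_max_rel = 0, r_max_diff = 0,
                pct_diff = numeric(0)))
  tab <- build_area_table(records, deltas)
  pd <- tab[tab$sex == "male" & !is.na(tab$pct_diff), ]
  pct_rel <- 0
  pd_first <- numeric(0)
  if (nrow(pd)) {
    spread <- tapply(pd$pct_diff, pd$age_group, function(v)
      (max(v) - min(v)) / max(abs(v)))
    pct_rel <- max(spread)
    first <- pd[pd$delta == deltas[1L], ]
    pd_first <- stats::setNames(first$pct_diff, first$age_group)
  }
  r_diff <- 0
  for (s in unique(tab$sex)) {
    rs <- vapply(deltas, function(d) {
      sub <- tab[tab$sex == s & tab$delta == d & !(tab$age_group %in% exclude), ]
      if (nrow(sub) < 3L) return(NA_real_)
      stats::cor(sub$V_dn, sub$area)
    }, numeric(1))
    rs <- rs[is.finite(rs)]
    if (length(rs) >= 2L) r_diff <- max(r_diff, max(rs) - min(rs))
  }
  list(pass = pct_rel < 1e-9 && r_diff < 1e-12,
       pct_diff_max_rel = pct_rel, r_max_diff = r_diff,
       pct_diff = pd_first)
}
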