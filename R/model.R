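#' Fit the LV surface-area model to a cohort table
#'
#' The central entry point: applies the truncated-prolate-spheroid LV model
#' to a sex- and age-stratified cohort table at each requested axis ratio,
#' and assembles the full analysis — per-row surface areas and TPS axes,
#' male/female percentage differences per age group, the signed comparison
#' of aggregate areas against an external reference area, the per-sex
#' Pearson correlation (with Student-t significance and regression line) of
#' surface area against normalized end-diastolic volume across age groups,
#' and a numerical check that percentage differences and correlations are
#' invariant in the axis ratio.
#'
#' @param data cohort data frame (`sex`, `age_group`, `D_d`, `V_dn`);
#'   defaults to the bundled MRI reference cohort.
#' @param deltas axis-ratio values in `(0, 1)` to simulate; default the
#'   normal-range endpoints plus the mid value commonly used in ventricular
#'   mass formulas, `c(0.45, 0.50, 0.62)`.
#' @param reference_area external reference LV surface area (cm^2).
#' @param exclude age-group labels treated as aggregates and excluded from
#'   correlations (default `"total"`).
#' @param tails tail count for correlation p-values (see
#'   [pearson_with_significance()]).
#' @return Object of class `"lv_area_model"`: a list with components
#'   `data`, `deltas`, `table` (see [build_area_table()]), `pct_diff`
#'   (named per-age-group percentages), `correlations` (named list of
#'   [pearson_with_significance()] results per sex, computed at
#'   `deltas[1]`), `reference` (data frame of aggregate-row comparisons per
#'   sex and delta), `invariance` (see [delta_invariance_check()]),
#'   `reference_area`, `exclude`, `call`.
#' @seealso [summary.lv_area_model()], [plot.lv_area_model()],
#'   [predict.lv_area_model()], [simulate.lv_area_model()]
#' @export
#' @examples
#' fit <- lv_area_model()
#' fit
#' summary(fit)
#' coef(fit)
lv_area_model <- function(data = builtin_reference_cohort(),
                          deltas = lv_config()$deltas,
                          reference_area = lv_config()$reference_area,
                          exclude = "total", tails = 2) {
  .validate_cohort(data)
  tab <- build_area_table(data, deltas)

  cors <- list()
  d1 <- deltas[1L]
  for (s in sort(unique(tab$sex))) {
    sub <- tab[tab$sex == s & tab$delta == d1 &
                 !(tab$age_group %in% exclude), ]
    if (nrow(sub) >= 3L && stats::sd(sub$V_dn) > 0 && stats::sd(sub$area) > 0)
      cors[[s]] <- pearson_with_significance(sub$V_dn, sub$area,
                                             tails = tails)
  }

  agg <- tab[tab$age_group %in% exclude, ]
  reference <- if (nrow(agg))
    data.frame(sex = agg$sex, delta = agg$delta, area = agg$area,
               pct_vs_reference = compare_to_reference(agg$area,
                                                       reference_area))
  else
    data.frame(sex = character(0), delta = numeric(0), area = numeric(0),
               pct_vs_reference = numeric(0))

  inv <- delta_invariance_check(data, deltas, exclude = exclude)
  first <- tab[tab$delta == d1 & tab$sex == "male" & !is.na(tab$pct_diff), ]
  pct <- stats::setNames(first$pct_diff, first$age_group)

  structure(list(data = data, deltas = deltas, table = tab,
                 pct_diff = pct, correlations = cors,
                 reference = reference, invariance = inv,
                 reference_area = reference_area, exclude = exclude,
                 call = match.call()),
            class = "lv_area_model")
}

#' @export
print.lv_area_model <- function(x, ...) {
  cat("LV surface-area model (truncated prolate spheroid)\n")
  cat(sprintf("  cohort: %d rows (%s), deltas: %s\n",
              nrow(x$data), paste(sort(unique(x$data$sex)), collapse = ", "),
              paste(format(x$deltas), collapse = ", ")))
  for (s in names(x$correlations))
    cat(sprintf("  %s area-volume correlation: r = %.4f (p = %.4f, df = %d)\n",
                s, x$correlations[[s]]$r, x$correlations[[s]]$p_value,
                x$correlations[[s]]$df))
  invisible(x)
}

#' Summarize an LV surface-area model
#'
#' Produces the blocked per-delta area table (age group by sex, with
#' \eqn{|\sigma|}, area and male/female percentage difference), the
#' comparison of aggregate areas against the external reference, the
#' per-sex correlations, and the delta-invariance check.
#'
#' @param object an [lv_area_model()] fit.
#' @param digits display rounding (the underlying numbers keep full
#'   precision; rounding is applied only here).
#' @param ... unused.
#' @return Object of class `"summary.lv_area_model"`.
#' @export
summary.lv_area_model <- function(object, digits = lv_config()$round_digits,
                                  ...) {
  structure(list(model = object, digits = digits),
            class = "summary.lv_area_model")
}

#' @export
print.summary.lv_area_model <- function(x, ...) {
  m <- x$model
  dg <- x$digits
  tab <- m$table
  for (d in m$deltas) {
    cat(sprintf("\ndelta = %.2f\n", d))
    sub <- tab[tab$delta == d, ]
    groups <- unique(sub$age_group)
    men <- sub[match(groups, ifelse(sub$sex == "male", sub$age_group, NA)), ]
    wom <- sub[match(groups, ifelse(sub$sex == "female", sub$age_group, NA)), ]
    block <- data.frame(age_group = groups,
                        men_abs_sigma = round(men$abs_sigma, dg),
                        men_area = round(men$area, dg),
                        women_abs_sigma = round(wom$abs_sigma, dg),
                        women_area = round(wom$area, dg),
                        pct_diff = round(ifelse(is.na(men$pct_diff),
                                                wom$pct_diff, men$pct_diff),
                                         dg))
    print(block, row.names = FALSE)
  }
  if (nrow(m$reference)) {
    cat(sprintf("\nComparison with the %.0f cm^2 reference area:\n",
                m$reference_area))
    ref <- m$reference
    ref$area <- round(ref$area, dg)
    ref$pct_vs_reference <- round(ref$pct_vs_reference, dg)
    print(ref, row.names = FALSE)
  }
  for (s in names(m$correlations)) {
    cat(sprintf("\n%s: area vs normalized end-diastolic volume\n", s))
    print(m$correlations[[s]])
  }
  cat(sprintf("\ndelta-invariance: %s (pct-diff spread %.2e, r spread %.2e)\n",
              if (m$invariance$pass) "holds" else "VIOLATED",
              m$invariance$pct_diff_max_rel, m$invariance$r_max_diff))
  invisible(x)
}

#' @export
coef.lv_area_model <- function(object, ...) {
  if (!length(object$correlations)) return(NULL)
  t(vapply(object$correlations,
           function(cr) c(intercept = cr$intercept, slope = cr$slope),
           numeric(2)))
}

#' Predict LV surface areas
#'
#' With `newdata` containing `D_d` (cm) and optionally `delta`, predicts
#' geometrically via [lv_surface_area()]. With `newdata` containing `V_dn`
#' and `sex` (and no `D_d`), predicts from the fitted per-sex regression of
#' area on normalized volume.
#'
#' @param object an [lv_area_model()] fit.
#' @param newdata data frame; `NULL` returns the fitted area table.
#' @param delta axis ratio used when `newdata` lacks a `delta` column.
#' @param ... unused.
#' @return Numeric vector of areas (cm^2), or the area table if
#'   `newdata` is `NULL`.
#' @export
predict.lv_area_model <- function(object, newdata = NULL,
                                  delta = object$deltas[1L], ...) {
  if (is.null(newdata)) return(object$table)
  if ("D_d" %in% names(newdata)) {
    d <- if ("delta" %in% names(newdata)) newdata$delta else delta
    return(suppressWarnings(lv_surface_area(newdata$D_d, d)))
  }
  if (all(c("V_dn", "sex") %in% names(newdata))) {
    out <- rep(NA_real_, nrow(newdata))
    for (s in unique(newdata$sex)) {
      cr <- object$correlations[[s]]
      if (is.null(cr)) stop("no fitted correlation for sex ", s,
                            call. = FALSE)
      i <- newdata$sex == s
      out[i] <- cr$intercept + cr$slope * newdata$V_dn[i]
    }
    return(out)
  }
  stop("'newdata' must contain D_d (geometric) or V_dn and sex (regression)",
       call. = FALSE)
}

#' @export
residuals.lv_area_model <- function(object, ...) {
  tab <- object$table
  d1 <- object$deltas[1L]
  out <- numeric(0)
  for (s in names(object$correlations)) {
    cr <- object$correlations[[s]]
    sub <- tab[tab$sex == s & tab$delta == d1 &
                 !(tab$age_group %in% object$exclude), ]
    r <- sub$area - (cr$intercept + cr$slope * sub$V_dn)
    names(r) <- paste(s, sub$age_group)
    out <- c(out, r)
  }
  out
}

#' Dispersion and regression plot of area against normalized volume
#'
#' Scatter of the age-group LV surface areas against the normalized
#' end-diastolic volumes, one panel per sex, with the fitted least-squares
#' line and the correlation annotated.
#'
#' @param x an [lv_area_model()] fit.
#' @param delta which axis ratio's areas to plot (default the first
#'   fitted).
#' @param ... further arguments passed to [graphics::plot()].
#' @return Invisibly, `x`.
#' @export
plot.lv_area_model <- function(x, delta = x$deltas[1L], ...) {
  sexes <- names(x$correlations)
  if (!length(sexes)) stop("no fitted correlations to plot", call. = FALSE)
  tab <- x$table
  old <- graphics::par(mfrow = c(1, length(sexes)))
  on.exit(graphics::par(old))
  for (s in sexes) {
    sub <- tab[tab$sex == s & tab$delta == delta &
                 !(tab$age_group %in% x$exclude), ]
    cr <- pearson_with_significance(sub$V_dn, sub$area)
    graphics::plot(sub$V_dn, sub$area,
                   xlab = expression(V[dn] ~ (mL/m^2)),
                   ylab = expression(A[sigma](S) ~ (cm^2)),
                   main = sprintf("%s (delta = %.2f), r = %.4f",
                                  s, delta, cr$r), pch = 19, ...)
    graphics::abline(cr$intercept, cr$slope)
    graphics::text(sub$V_dn, sub$area, sub$age_group, pos = 3, cex = 0.7)
  }
  invisible(x)
}

#' Simulate synthetic cohorts from a fitted model
#'
#' Draws synthetic cohorts whose group structure matches the fitted data
#' (age-group diameters as group means) and whose volume-diameter coupling
#' \eqn{V_{dn} = \alpha + \beta D^2 + \varepsilon} is re-fitted from the
#' data's age-group rows, via [simulate_cohort()].
#'
#' @param object an [lv_area_model()] fit.
#' @param nsim number of cohorts to draw.
#' @param seed optional integer seed.
#' @param sd_D per-subject diameter standard deviation (cm).
#' @param n_per_group subjects per group.
#' @param ... unused.
#' @return List of `nsim` cohort data frames.
#' @export
simulate.lv_area_model <- function(object, nsim = 1, seed = NULL,
                                   sd_D = 0.4, n_per_group = 10L, ...) {
  dat <- object$data[!(object$data$age_group %in% object$exclude), ]
  fit <- stats::lm.fit(cbind(1, dat$D_d^2), dat$V_dn)
  tau <- sqrt(sum(fit$residuals^2) / max(nrow(dat) - 2L, 1L))
  groups <- data.frame(sex = dat$sex, age_group = dat$age_group,
                       mean_D = dat$D_d, sd_D = sd_D)
  if (!is.null(seed)) set.seed(as.integer(seed))
  lapply(seq_len(nsim), function(i)
    simulate_cohort(groups, alpha = fit$coefficients[1L],
                    beta = fit$coefficients[2L], tau = tau,
                    n_per_group = n_per_group, seed = NULL))
}
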