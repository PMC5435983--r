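# CSV input/output for cohort tables, the bundled MRI reference cohort,
# the synthetic-cohort generator, and JSON configuration.

# Age-group labels arrive in several typographic variants across published
# tables; normalize to a canonical hyphenated form so sexes pair by label.
.normalize_age_group <- function(x) {
  x <- trimws(x)
  x <- gsub("–|—", "-", x)               # en/em dash -> hyphen
  x[tolower(x) == "total"] <- "total"
  x[x %in% c("≥60", ">=60", "60+")] <- "60-69"
  x
}

#' Read a cohort table from CSV
#'
#' Expects a UTF-8, comma-delimited, decimal-point file with header columns
#' `sex` (`female`/`male`), `age_group`, `D_d_cm` and `V_dn_ml_m2`.
#' Validation failures report the offending data row number. Age-group
#' labels are normalized (dash variants and the `">=60"`/`"60+"` aliases
#' map to `"60-69"`; `"Total"` to `"total"`).
#'
#' @param path path to the CSV file.
#' @return Data frame with columns `sex`, `age_group`, `D_d` (cm), `V_dn`
#'   (mL/m^2); zero rows if the file holds only a header.
#' @seealso [write_cohort_csv()], [builtin_reference_cohort()]
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path))
    stop("no such file: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character",
                         fileEncoding = "UTF-8", strip.white = TRUE)
  needed <- c("sex", "age_group", "D_d_cm", "V_dn_ml_m2")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols))
    stop("missing column(s) in ", path, ": ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (nrow(raw) == 0L)
    return(data.frame(sex = character(0), age_group = character(0),
                      D_d = numeric(0), V_dn = numeric(0)))
  sex <- tolower(raw$sex)
  bad <- which(!sex %in% c("female", "male"))
  if (length(bad))
    stop("row ", bad[1L], ": unknown sex label \"", raw$sex[bad[1L]], "\"",
         call. = FALSE)
  num <- function(col, name, rows = seq_len(nrow(raw))) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(!is.finite(v))
    if (length(bad))
      stop("row ", bad[1L], ": cannot parse ", name, " value \"",
           raw[[col]][bad[1L]], "\"", call. = FALSE)
    bad <- which(v <= 0)
    if (length(bad))
      stop("row ", bad[1L], ": ", name, " must be positive (got ",
           v[bad[1L]], ")", call. = FALSE)
    v
  }
  out <- data.frame(sex = sex,
                    age_group = .normalize_age_group(raw$age_group),
                    D_d = num("D_d_cm", "D_d"),
                    V_dn = num("V_dn_ml_m2", "V_dn"))
  .validate_cohort(out)
  out
}

#' Write a cohort table to CSV
#'
#' Inverse of [read_cohort_csv()]: writes the canonical schema
#' (`sex`, `age_group`, `D_d_cm`, `V_dn_ml_m2`) so that a write/read
#' round trip is the identity on records.
#'
#' @param records cohort data frame (`sex`, `age_group`, `D_d`, `V_dn`).
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_cohort_csv <- function(records, path) {
  .validate_cohort(records)
  out <- data.frame(sex = records$sex, age_group = records$age_group,
                    D_d_cm = records$D_d, V_dn_ml_m2 = records$V_dn)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Bundled MRI reference cohort
#'
#' The sex- and age-stratified averages of LV end-diastolic short-axis
#' diameter (`D_d`, cm) and end-diastolic volume normalized by body surface
#' area (`V_dn`, mL/m^2) from a published MRI study of 107 normal Brazilian
#' adults (54 men, 53 women): a `total` row plus five decade age groups per
#' sex, 12 rows in all.
#'
#' @return Cohort data frame (see [read_cohort_csv()] for columns).
#' @export
#' @examples
#' builtin_reference_cohort()
builtin_reference_cohort <- function() {
  read_cohort_csv(system.file("extdata", "macedo_lv_reference.csv",
                              package = "lvtps", mustWork = TRUE))
}

#' Default per-group structure for the synthetic-cohort generator
#'
#' The ten sex-by-decade cells of the bundled reference cohort
#' (aggregate `total` rows dropped), with the reference diameters as group
#' means and a common per-subject diameter standard deviation.
#'
#' @param sd_D per-subject standard deviation of the end-diastolic diameter
#'   within a group (cm).
#' @return Data frame with columns `sex`, `age_group`, `mean_D`, `sd_D`.
#' @seealso [simulate_cohort()]
#' @export
reference_cohort_groups <- function(sd_D = 0.4) {
  ref <- builtin_reference_cohort()
  ref <- ref[!(ref$age_group %in% .aggregate_labels), ]
  data.frame(sex = ref$sex, age_group = ref$age_group,
             mean_D = ref$D_d, sd_D = sd_D)
}

#' Simulate a synthetic cohort with a linear volume-diameter-squared coupling
#'
#' Generates per-subject end-diastolic diameters \eqn{D \sim N(\mu_g,
#' sd_D^2)} (truncated positive) within each group, couples the normalized
#' volume linearly to the squared diameter,
#' \eqn{V_{dn} = \alpha + \beta D^2 + \varepsilon}, with
#' \eqn{\varepsilon \sim N(0, \tau^2)} and truncation at positive values,
#' and (by default) returns per-group averages mimicking the structure of
#' the bundled reference table. Defaults emulate that table: group means
#' from [reference_cohort_groups()], and a coupling (`alpha` = 20.6
#' mL/m^2, `beta` = 2.14 mL/m^2 per cm^2, `tau` = 2.1 mL/m^2) fitted once
#' to its ten age-group rows.
#'
#' @param groups data frame with columns `sex`, `age_group`, `mean_D`
#'   (cm), `sd_D` (cm, non-negative).
#' @param alpha intercept of the volume coupling (mL/m^2).
#' @param beta slope of the volume coupling (mL/m^2 per cm^2).
#' @param tau standard deviation of the volume noise (mL/m^2),
#'   non-negative.
#' @param n_per_group subjects drawn per group (`>= 1`).
#' @param seed optional integer seed; the same seed reproduces the same
#'   cohort exactly.
#' @param aggregate if `TRUE` (default), return one averaged row per group
#'   (as reference tables do); if `FALSE`, one row per simulated subject.
#' @return Cohort data frame (`sex`, `age_group`, `D_d`, `V_dn`).
#' @export
#' @examples
#' simulate_cohort(seed = 1)
#' simulate_cohort(tau = 0, n_per_group = 1, seed = 1)  # noiseless coupling
simulate_cohort <- function(groups = reference_cohort_groups(),
                            alpha = 20.6, beta = 2.14, tau = 2.1,
                            n_per_group = 10L, seed = NULL,
                            aggregate = TRUE) {
  if (!is.data.frame(groups) || nrow(groups) == 0L ||
      !all(c("sex", "age_group", "mean_D", "sd_D") %in% names(groups)))
    stop("'groups' needs columns sex, age_group, mean_D, sd_D",
         call. = FALSE)
  if (any(groups$mean_D <= 0) || any(groups$sd_D < 0))
    stop("'mean_D' must be positive and 'sd_D' non-negative", call. = FALSE)
  if (!is.finite(tau) || tau < 0)
    stop("'tau' must be non-negative", call. = FALSE)
  n_per_group <- as.integer(n_per_group)
  if (is.na(n_per_group) || n_per_group < 1L)
    stop("'n_per_group' must be at least 1", call. = FALSE)
  if (!is.null(seed)) set.seed(as.integer(seed))

  draw_pos <- function(n, mean, sd) {
    if (sd == 0) return(rep(mean, n))
    v <- stats::rnorm(n, mean, sd)
    while (any(v <= 0)) v[v <= 0] <- stats::rnorm(sum(v <= 0), mean, sd)
    v
  }
  rows <- lapply(seq_len(nrow(groups)), function(i) {
    D <- draw_pos(n_per_group, groups$mean_D[i], groups$sd_D[i])
    V <- draw_pos_shifted(alpha + beta * D^2, tau)
    if (aggregate)
      data.frame(sex = groups$sex[i], age_group = groups$age_group[i],
                 D_d = mean(D), V_dn = mean(V))
    else
      data.frame(sex = groups$sex[i],
                 age_group = paste0(groups$age_group[i], "/",
                                    seq_len(n_per_group)),
                 D_d = D, V_dn = V)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# positive-truncated N(mu_i, tau) draws, vectorized over mu
draw_pos_shifted <- function(mu, tau) {
  if (tau == 0) return(mu)
  v <- stats::rnorm(length(mu), mu, tau)
  while (any(v <= 0)) v[v <= 0] <- stats::rnorm(sum(v <= 0), mu[v <= 0], tau)
  v
}

#' Package configuration
#'
#' Analysis-level settings: the axis-ratio values simulated, the external
#' reference area (cm^2) used by [compare_to_reference()], display rounding
#' digits, and the normal axis-ratio band. `lv_config()` returns the
#' defaults, optionally merged with overrides from a JSON file.
#'
#' @param path optional path to a JSON file whose top-level keys override
#'   the defaults (unknown keys are rejected).
#' @return Named list: `deltas`, `reference_area`, `round_digits`,
#'   `delta_normal_range`.
#' @export
lv_config <- function(path = NULL) {
  cfg <- list(deltas = c(0.45, 0.50, 0.62),
              reference_area = 151,
              round_digits = 2L,
              delta_normal_range = unname(lv_delta_normal_range()))
  if (!is.null(path)) {
    if (!file.exists(path)) stop("no such config file: ", path, call. = FALSE)
    user <- jsonlite::read_json(path, simplifyVector = TRUE)
    unknown <- setdiff(names(user), names(cfg))
    if (length(unknown))
      stop("unknown config key(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    cfg[names(user)] <- user
  }
  cfg
}
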