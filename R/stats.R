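#' Froude number of a walking gait
#'
#' Dimensionless speed `Fr = v^2 / (g * h)` with `h` the limb (hip) height;
#' used to compare gaits across body sizes. Walking elephants move around
#' Fr 0.05-0.10.
#'
#' @param velocity_ms Speed in m/s (vectorized).
#' @param height_m Limb height in m (vectorized).
#' @param g Gravitational acceleration, m/s^2.
#' @return Dimensionless Froude number(s).
#' @export
froude <- function(velocity_ms, height_m, g = 9.81) {
  if (any(height_m <= 0)) stop("`height_m` must be positive", call. = FALSE)
  if (any(velocity_ms < 0)) stop("`velocity_ms` must be non-negative", call. = FALSE)
  velocity_ms^2 / (g * height_m)
}

#' Weighted mean
#'
#' `sum(w * v) / sum(w)`; used e.g. for the step-weighted mean body mass of a
#' cohort (each subject's mass weighted by its number of sampled steps).
#'
#' @param values,weights Equal-length numeric vectors; weights non-negative,
#'   not all zero.
#' @return The weighted mean.
#' @export
weighted_mean <- function(values, weights) {
  if (length(values) != length(weights)) {
    stop("`values` and `weights` must have equal length", call. = FALSE)
  }
  if (any(weights < 0)) stop("weights must be non-negative", call. = FALSE)
  if (sum(weights) == 0) stop("weights must not all be zero", call. = FALSE)
  stats::weighted.mean(values, weights)
}

#' Group-wise mean and standard error
#'
#' Arithmetic mean and standard error (sample standard deviation with n - 1,
#' divided by sqrt(n)) of a value column per group, with group sizes. Groups
#' are never silently dropped: the sum of `n` equals the input row count.
#'
#' @param table Data frame (e.g. an ROI pressure table).
#' @param group_by Character vector of grouping column names.
#' @param value Name of the value column.
#' @return A [tibble::tibble()] with the group columns plus `mean`, `se`, `n`.
#' @export
summarize_pressures <- function(table, group_by,
                                value = "peak_pressure_kpa") {
  if (!value %in% names(table)) stop("no column ", value, call. = FALSE)
  missing <- setdiff(group_by, names(table))
  if (length(missing)) {
    stop("missing grouping column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  table |>
    dplyr::group_by(dplyr::across(dplyr::all_of(group_by))) |>
    dplyr::summarise(
      mean = mean(.data[[value]]),
      se = if (dplyr::n() > 1) stats::sd(.data[[value]]) / sqrt(dplyr::n()) else 0,
      n = dplyr::n(),
      .groups = "drop"
    )
}

#' Fore/hind pressure contrast
#'
#' Percentage by which the fore mean exceeds the hind mean:
#' `100 * (fore / hind - 1)`.
#'
#' @param fore_mean,hind_mean Mean peak pressures (kPa).
#' @return Contrast in percent.
#' @export
fore_hind_contrast <- function(fore_mean, hind_mean) {
  if (hind_mean <= 0) stop("`hind_mean` must be positive", call. = FALSE)
  100 * (fore_mean / hind_mean - 1)
}

#' Ratio of two cohort mean pressures
#'
#' @param mean_a_kpa,mean_b_kpa Cohort grand means (kPa); `mean_b_kpa > 0`.
#' @return `mean_a_kpa / mean_b_kpa`.
#' @export
cohort_ratio <- function(mean_a_kpa, mean_b_kpa) {
  if (mean_b_kpa <= 0) stop("denominator mean must be positive", call. = FALSE)
  mean_a_kpa / mean_b_kpa
}

#' Published subject characteristics of the African cohort
#'
#' Per-subject table of the five African elephants: estimated body mass,
#' shoulder height, foot circumferences, mean Froude number, mean velocity,
#' per-foot mean maximum pressures with standard errors, and the number of
#' sampled steps and trials. Shipped as plain CSV in `extdata`.
#'
#' @return A [tibble::tibble()] with one row per subject.
#' @export
african_subjects <- function() {
  path <- system.file("extdata", "african_subjects.csv", package = "pedopress",
                      mustWork = TRUE)
  types <- c(
    subject = "character", age_y = "numeric", sex = "character",
    body_mass_kg = "numeric", shoulder_height_m = "numeric",
    rff_circumference_m = "numeric", rhf_circumference_m = "numeric",
    froude = "numeric", velocity_ms = "numeric",
    mpp_fore_left_kpa = "numeric", mpp_fore_left_se = "numeric",
    mpp_fore_right_kpa = "numeric", mpp_fore_right_se = "numeric",
    mpp_hind_left_kpa = "numeric", mpp_hind_left_se = "numeric",
    mpp_hind_right_kpa = "numeric", mpp_hind_right_se = "numeric",
    n_steps = "integer", n_trials = "integer"
  )
  read_table(path, schema = types)
}

#' Published cohort-level reference values
#'
#' Grand mean peak pressures of the African and Asian cohorts, the fore and
#' hind grand means with standard errors, and Asian-cohort speed/mass
#' references, as a named numeric vector.
#'
#' @return Named numeric vector.
#' @export
published_cohort_values <- function() {
  path <- system.file("extdata", "published_cohort_values.csv",
                      package = "pedopress", mustWork = TRUE)
  tb <- read_table(path, schema = c(quantity = "character", value = "numeric"))
  stats::setNames(tb$value, tb$quantity)
}
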