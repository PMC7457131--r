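# anatomy module: claw-base area, static pressure, weight change,
# metabolic live-weight (livestock-unit) arithmetic.

KG_PER_CM2_TO_KPA <- 98.0665

#' Total claw-base area of one cow
#'
#' Claw outlines are traced for the left forefoot and left hindfoot only
#' (medial and lateral claw each); the left side proxies the right, so the
#' summed outline area is doubled.
#'
#' @param outlines A data frame of outline vertices for one cow with columns
#'   `foot` (`"fore"`/`"hind"`), `claw` (`"medial"`/`"lateral"`),
#'   `vertex_index`, `x_cm`, `y_cm`. Exactly the four left-side foot x claw
#'   combinations must be present.
#' @return Total claw-base area in cm^2 (twice the sum of the four outline
#'   areas).
#' @export
total_claw_base <- function(outlines) {
  check_cols(outlines, c("foot", "claw", "vertex_index", "x_cm", "y_cm"),
             "outlines")
  combos <- outlines |>
    distinct(.data$foot, .data$claw) |>
    mutate(key = paste(.data$foot, .data$claw))
  expected <- c("fore medial", "fore lateral", "hind medial", "hind lateral")
  missing <- setdiff(expected, combos$key)
  if (length(missing)) {
    abort_bad_arg(sprintf("missing claw outline(s): %s.",
                          paste(missing, collapse = ", ")),
                  class = "grazemetry_validation_error")
  }
  extra <- setdiff(combos$key, expected)
  if (length(extra)) {
    abort_bad_arg(sprintf("unknown foot/claw combination(s): %s.",
                          paste(extra, collapse = ", ")),
                  class = "grazemetry_validation_error")
  }
  areas <- outlines |>
    arrange(.data$vertex_index) |>
    group_by(.data$foot, .data$claw) |>
    summarise(area = polygon_area(.data$x_cm, .data$y_cm), .groups = "drop")
  2 * sum(areas$area)
}

#' Static claw pressure
#'
#' Body weight divided by the total claw-base area: the time-averaged load a
#' standing animal exerts per square centimetre of claw. Units are kg/cm^2
#' (mass loading; multiply by 98.0665 for kPa).
#'
#' @param weight Body weight in kg (vectorized).
#' @param claw_base Total claw-base area in cm^2 (vectorized).
#' @param as_kpa Return kPa instead of kg/cm^2.
#' @return Pressure in kg/cm^2 (or kPa).
#' @examples
#' static_pressure(640, 256) # 2.5 kg/cm^2
#' @export
static_pressure <- function(weight, claw_base, as_kpa = FALSE) {
  check_number(weight, "weight", positive = TRUE)
  check_number(claw_base, "claw_base", positive = TRUE)
  p <- weight / claw_base
  if (as_kpa) p * KG_PER_CM2_TO_KPA else p
}

#' Average daily body-weight change
#'
#' @param weight_start,weight_end Weights in kg at turn-out and at the end of
#'   the grazing period (vectorized).
#' @param days Days between the two weighings (>= 1).
#' @return Signed change in kg/day.
#' @export
daily_weight_change <- function(weight_start, weight_end, days) {
  check_number(weight_start, "weight_start", positive = TRUE)
  check_number(weight_end, "weight_end", positive = TRUE)
  check_number(days, "days")
  if (any(days < 1)) abort_bad_arg("`days` must be >= 1.")
  (weight_end - weight_start) / days
}

#' Metabolic livestock units
#'
#' Normalizes metabolic body mass (W^0.75) to a reference cow:
#' LU = (W / reference)^0.75. With the conventional 600 kg reference a
#' 600 kg cow is exactly 1 LU.
#'
#' @param weight Body weight in kg (vectorized).
#' @param reference Reference weight in kg (default 600).
#' @return Livestock units (dimensionless).
#' @examples
#' metabolic_lu(c(358, 600, 679))
#' @export
metabolic_lu <- function(weight, reference = 600) {
  check_number(weight, "weight", positive = TRUE)
  check_number(reference, "reference", positive = TRUE)
  (weight / reference)^0.75
}

#' Stocking density in livestock units per hectare
#'
#' @param lus Vector of per-animal livestock units (non-empty).
#' @param area_ha Grazed area in hectares (> 0).
#' @return LU/ha.
#' @export
stocking_density <- function(lus, area_ha) {
  if (length(lus) == 0) abort_bad_arg("`lus` must contain at least one animal.")
  check_number(lus, "lus", positive = TRUE)
  check_number(area_ha, "area_ha", positive = TRUE)
  sum(lus) / area_ha
}

#' Per-cow anatomy metrics
#'
#' Combines cow records and claw outlines into the per-cow anatomy table:
#' total claw-base area, static pressure (end-of-season weight by default),
#' average daily weight change, and metabolic livestock units.
#'
#' @param cows A data frame with columns `cow_id`, `breed`, `weight_start`,
#'   `weight_end`, `days_on_pasture`.
#' @param outlines Claw-outline vertices for all cows (columns as in
#'   [total_claw_base()] plus `cow_id`).
#' @param pressure_weight Which weight enters the pressure: `"end"`
#'   (default; claw base is measured at the end of the season) or `"start"`.
#' @param lu_reference Reference weight for [metabolic_lu()].
#' @return A tibble with one row per cow: `cow_id`, `breed`,
#'   `claw_base_total`, `static_pressure`, `daily_weight_change`,
#'   `metabolic_lu`.
#' @export
anatomy_metrics <- function(cows, outlines, pressure_weight = c("end", "start"),
                            lu_reference = 600) {
  pressure_weight <- match.arg(pressure_weight)
  check_cols(cows, c("cow_id", "breed", "weight_start", "weight_end",
                     "days_on_pasture"), "cows")
  check_cols(outlines, c("cow_id", "foot", "claw", "vertex_index",
                         "x_cm", "y_cm"), "outlines")
  claw <- outlines |>
    group_by(.data$cow_id) |>
    dplyr::group_modify(~ tibble(claw_base_total = total_claw_base(.x))) |>
    ungroup()
  out <- cows |>
    as_tibble() |>
    left_join(claw, by = "cow_id")
  if (anyNA(out$claw_base_total)) {
    abort_bad_arg(sprintf(
      "no claw outlines for cow(s): %s.",
      paste(out$cow_id[is.na(out$claw_base_total)], collapse = ", ")
    ), class = "grazemetry_validation_error")
  }
  w <- if (pressure_weight == "end") out$weight_end else out$weight_start
  out |>
    mutate(
      static_pressure = static_pressure(w, .data$claw_base_total),
      daily_weight_change = daily_weight_change(.data$weight_start,
                                                .data$weight_end,
                                                .data$days_on_pasture),
      metabolic_lu = metabolic_lu(.data$weight_end, lu_reference)
    ) |>
    select(all_of(c("cow_id", "breed", "claw_base_total", "static_pressure",
                    "daily_weight_change", "metabolic_lu")))
}
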