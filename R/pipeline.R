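# pipeline: bundle -> per-cow metrics -> breed comparisons -> allometry
# report

#' Default allometric variable pairs
#'
#' The nine trait pairs examined across anatomy, movement and foraging:
#' claw base against body weight, weight change against diet quality,
#' lying against selection evenness, space-use evenness against selection
#' evenness and diet quality, diet quality against selection evenness, and
#' step rate against space-use evenness, selection evenness and diet
#' quality.
#'
#' @return A tibble `pair`, `x`, `y` of cow-mean column names.
#' @export
default_allometry_pairs <- function() {
  tibble(
    pair = LETTERS[1:9],
    x = c("weight_end", "quality_score", "selection_evenness",
          "selection_evenness", "quality_score", "selection_evenness",
          "camargo_evenness", "selection_evenness", "quality_score"),
    y = c("claw_base_total", "daily_weight_change", "lying_ratio",
          "camargo_evenness", "camargo_evenness", "quality_score",
          "steps_per_h", "steps_per_h", "steps_per_h")
  )
}

#' Run the full analysis pipeline on a study bundle
#'
#' Computes anatomy, movement and diet metrics per cow (per paddock /
#' pasture where applicable), averages movement and foraging variables per
#' cow over pastures, runs Tukey range tests among breeds (on the cow
#' means and within each pasture), the breed x paddock-size ANOVA for
#' movement variables, and grouped SMA allometries for the configured
#' variable pairs.
#'
#' @param bundle A `study_bundle` from [simulate_study()] or
#'   [read_study()].
#' @param pairs Allometry pairs (default [default_allometry_pairs()]).
#' @param cell_size Occupancy grid cell edge in metres (default 5).
#' @param max_speed_kmh GPS error speed cutoff (default 10).
#' @param tukey_vars Variables tested among breeds; default: the anatomy,
#'   movement and foraging headline variables.
#' @return A `study_report` with elements `cow_pasture` (per cow x
#'   pasture), `cow_means` (one row per cow), `tukey`, `anova`,
#'   `allometry` (glance table), `sma` (named list of [sma_group_test()]
#'   objects), `meta`.
#' @export
run_study <- function(bundle, pairs = default_allometry_pairs(),
                      cell_size = 5, max_speed_kmh = 10,
                      tukey_vars = c("weight_end", "claw_base_total",
                                     "static_pressure", "daily_weight_change",
                                     "steps_per_h", "speed_m_h", "lying_ratio",
                                     "camargo_evenness", "slope_coef",
                                     "water_coef", "selection_evenness",
                                     "quality_score")) {
  stopifnot(inherits(bundle, "study_bundle"))
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e) {
      abort_bad_arg(sprintf("[%s] %s", what, conditionMessage(e)),
                    class = class(e)[1])
    })
  }
  anatomy <- stage("anatomy", anatomy_metrics(bundle$cows,
                                              bundle$claw_outlines))
  movement <- stage("movement", movement_metrics(bundle$gps, bundle$pedometer,
                                                 bundle$paddocks, cell_size,
                                                 max_speed_kmh))
  pad_pasture <- tibble(
    paddock_id = names(bundle$paddocks),
    pasture_id = vapply(bundle$paddocks, function(p) p$pasture_id,
                        character(1)),
    paddock_ha = vapply(bundle$paddocks, function(p) p$area_ha, numeric(1))
  )
  movement <- movement |> left_join(pad_pasture, by = "paddock_id")
  diets <- stage("foraging", diet_profiles(bundle$bites, bundle$taxa))
  cow_pasture <- movement |>
    dplyr::full_join(diets, by = c("cow_id", "pasture_id")) |>
    left_join(select(bundle$cows, all_of(c("cow_id", "breed"))),
              by = "cow_id")
  mean_vars <- c("speed_m_h", "distance_m", "steps_per_h", "lying_ratio",
                 "camargo_evenness", "slope_coef", "water_coef",
                 "quality_score", "selection_evenness",
                 grep("^share_", names(cow_pasture), value = TRUE))
  cow_means <- cow_pasture |>
    group_by(.data$cow_id, .data$breed) |>
    summarise(across(all_of(mean_vars), ~ mean(.x, na.rm = TRUE)),
              .groups = "drop") |>
    left_join(anatomy |> select(-all_of("breed")), by = "cow_id") |>
    left_join(select(bundle$cows, all_of(c("cow_id", "weight_start",
                                           "weight_end"))), by = "cow_id")
  # Tukey range tests among breeds: cow means, then per pasture
  tukey <- stage("compare", {
    per_cow <- purrr::map_dfr(intersect(tukey_vars, names(cow_means)),
                              function(v) {
      tukey_pairwise(cow_means, !!rlang::sym(v), breed) |>
        mutate(variable = v, scope = "overall", .before = 1)
    })
    pasture_vars <- intersect(tukey_vars, names(cow_pasture))
    per_pasture <- purrr::map_dfr(unique(cow_pasture$pasture_id), function(p) {
      sub <- filter(cow_pasture, .data$pasture_id == p)
      purrr::map_dfr(pasture_vars, function(v) {
        if (all(is.na(sub[[v]]))) return(NULL)
        tukey_pairwise(sub, !!rlang::sym(v), breed) |>
          mutate(variable = v, scope = p, .before = 1)
      })
    })
    bind_rows(per_cow, per_pasture)
  })
  # breed x paddock size ANOVA on movement variables
  anova_tbl <- stage("compare", {
    purrr::map_dfr(intersect(c("steps_per_h", "distance_m",
                               "camargo_evenness"), names(cow_pasture)),
                   function(v) {
      sub <- cow_pasture[!is.na(cow_pasture[[v]]), ]
      anova_breed_size(sub, !!rlang::sym(v), breed, paddock_ha) |>
        mutate(response = v, .before = 1)
    })
  })
  # grouped SMA allometries
  sma_list <- list(); allo_rows <- list()
  for (k in seq_len(nrow(pairs))) {
    xv <- pairs$x[k]; yv <- pairs$y[k]
    label <- pairs$pair[k]
    if (!xv %in% names(cow_means) || !yv %in% names(cow_means)) {
      allo_rows[[label]] <- tibble(pair = label, x = xv, y = yv,
                                   status = "missing variable")
      next
    }
    res <- tryCatch(
      sma_group_test(cow_means, !!rlang::sym(xv), !!rlang::sym(yv), breed),
      grazemetry_degenerate_error = function(e) e
    )
    if (inherits(res, "error")) {
      allo_rows[[label]] <- tibble(pair = label, x = xv, y = yv,
                                   status = "degenerate")
      next
    }
    overall <- sma_fit_xy(cow_means[[xv]], cow_means[[yv]],
                          x_name = xv, y_name = yv)
    sma_list[[label]] <- res
    allo_rows[[label]] <- dplyr::bind_cols(
      tibble(pair = label, x = xv, y = yv, status = "ok",
             overall_slope = overall$slope, overall_r2 = overall$r_squared),
      glance(res)
    )
  }
  meta <- list(
    seed = bundle$config$seed,
    config_hash = rlang::hash(bundle$config),
    n_cows = nrow(bundle$cows),
    n_paddocks = length(bundle$paddocks)
  )
  structure(
    list(cow_pasture = cow_pasture, cow_means = cow_means,
         anatomy = anatomy, tukey = tukey, anova = anova_tbl,
         allometry = bind_rows(allo_rows), sma = sma_list, meta = meta),
    class = "study_report"
  )
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("<study_report: %d cows, %d allometry pairs (%d fitted)>\n",
              nrow(x$cow_means), nrow(x$allometry), length(x$sma)))
  invisible(x)
}

#' Allometry summary of a study report
#'
#' One row per configured variable pair with the overall SMA fit and the
#' grouped slope/shift/elevation test results; pairs whose variables are
#' missing or degenerate (zero variance) are flagged in `status` rather
#' than dropped.
#'
#' @param report A `study_report`.
#' @return A tibble.
#' @export
allometry_pairs <- function(report) {
  stopifnot(inherits(report, "study_report"))
  report$allometry
}

#' Result tables of a study report
#'
#' @param report A `study_report`.
#' @return A named list of tibbles suitable for [write_results()].
#' @export
report_tables <- function(report) {
  stopifnot(inherits(report, "study_report"))
  list(
    cow_pasture = report$cow_pasture,
    cow_means = report$cow_means,
    tukey = report$tukey,
    anova = report$anova,
    allometry = report$allometry
  )
}
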