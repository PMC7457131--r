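# assembly of a full synthetic grazing study: default alpine taxon table,
# pasture specifications, and the (seed, config)-deterministic bundle

#' Default alpine taxon table
#'
#' A compact set of alpine pasture taxa with Briemle-style forage-quality
#' indicator values (1 = worthless, 9 = best forage) and coarse plant
#' groups, including two field-recording group taxa (broad- and
#' fine-leaved Poaceae) whose per-pasture effective quality is resolved
#' from relevee abundances of their member species.
#'
#' @return A [taxon_table()].
#' @export
alpine_taxa <- function() {
  taxa <- tibble(
    taxon_id = c("broad_poaceae", "fine_poaceae",
                 "trisetum_flavescens", "phleum_rhaeticum",
                 "festuca_rubra", "agrostis_capillaris",
                 "deschampsia_cespitosa", "nardus_stricta",
                 "trifolium_pratense", "cirsium_spinosissimum",
                 "calluna_vulgaris", "vaccinium_myrtillus",
                 "alchemilla_xanthochlora", "ranunculus_acris"),
    kind = c("group", "group", rep("species", 12)),
    quality = c(NA, NA, 7, 8, 6, 5, 3, 2, 8, 2, 1, 2, 6, 4),
    plant_group = c("broad_grass", "fine_grass",
                    "broad_grass", "broad_grass",
                    "fine_grass", "fine_grass",
                    "broad_grass", "fine_grass",
                    "legume", "thistle",
                    "shrub", "shrub",
                    "other", "other")
  )
  members <- dplyr::bind_rows(
    tidyr::expand_grid(pasture_id = c("P1", "P2", "P3"),
                       tibble(group_id = "broad_poaceae",
                              member_id = c("trisetum_flavescens",
                                            "phleum_rhaeticum"))) |>
      mutate(abundance = dplyr::case_when(
        .data$pasture_id == "P1" & .data$member_id == "trisetum_flavescens" ~ 0.6,
        .data$pasture_id == "P1" ~ 0.4,
        .data$pasture_id == "P2" & .data$member_id == "trisetum_flavescens" ~ 0.5,
        .data$pasture_id == "P2" ~ 0.5,
        .data$pasture_id == "P3" & .data$member_id == "trisetum_flavescens" ~ 0.7,
        TRUE ~ 0.3
      )),
    tidyr::expand_grid(pasture_id = c("P1", "P2", "P3"),
                       tibble(group_id = "fine_poaceae",
                              member_id = c("festuca_rubra",
                                            "agrostis_capillaris"))) |>
      mutate(abundance = dplyr::if_else(.data$member_id == "festuca_rubra",
                                        0.5, 0.5))
  )
  taxon_table(taxa, members)
}

#' Default pasture specifications
#'
#' Three pasture types spanning a productivity gradient, each split into
#' one paddock per breed (the low-demand breed gets the smallest paddock
#' so that metabolic stocking densities stay comparable): a nutrient-rich
#' flat pasture, a heterogeneous steep pasture with a thistle component,
#' and a nutrient-poor steep shrub/fen pasture.
#'
#' @param breeds Character vector of breed codes (paddock per breed).
#' @return A list of [make_pasture()] specs (one per paddock).
#' @export
default_pasture_specs <- function(breeds = c("AH", "OB", "HC")) {
  avail <- list(
    P1 = tibble(
      taxon_id = c("broad_poaceae", "trifolium_pratense", "fine_poaceae",
                   "alchemilla_xanthochlora", "ranunculus_acris",
                   "deschampsia_cespitosa", "nardus_stricta",
                   "cirsium_spinosissimum"),
      abundance = c(0.35, 0.25, 0.15, 0.10, 0.05, 0.05, 0.03, 0.02)
    ),
    P2 = tibble(
      taxon_id = c("broad_poaceae", "fine_poaceae", "nardus_stricta",
                   "deschampsia_cespitosa", "trifolium_pratense",
                   "cirsium_spinosissimum", "calluna_vulgaris",
                   "vaccinium_myrtillus"),
      abundance = c(0.15, 0.25, 0.15, 0.10, 0.08, 0.12, 0.10, 0.05)
    ),
    P3 = tibble(
      taxon_id = c("calluna_vulgaris", "vaccinium_myrtillus",
                   "nardus_stricta", "deschampsia_cespitosa",
                   "fine_poaceae", "broad_poaceae",
                   "cirsium_spinosissimum"),
      abundance = c(0.25, 0.20, 0.20, 0.10, 0.15, 0.05, 0.05)
    )
  )
  sizes <- list(P1 = c(AH = 0.39, OB = 0.39, HC = 0.27),
                P2 = c(AH = 0.70, OB = 0.69, HC = 0.43),
                P3 = c(AH = 1.66, OB = 1.71, HC = 1.01))
  slopes <- c(P1 = 19.2, P2 = 48.1, P3 = 25.1)
  n_water <- c(P1 = 1, P2 = 2, P3 = 3)
  specs <- list()
  for (p in names(avail)) {
    for (b in breeds) {
      specs[[paste(p, b, sep = "-")]] <- list(
        paddock_id = paste(p, b, sep = "-"), pasture_id = p,
        size_ha = unname(sizes[[p]][b]),
        mean_slope_pct = unname(slopes[p]),
        n_water = unname(n_water[p]),
        availability = avail[[p]]
      )
    }
  }
  specs
}

#' Configuration of a synthetic grazing study
#'
#' @param seed Master seed (mandatory; every stage derives its own child
#'   seed from it, so (seed, config) fully determines the bundle).
#' @param n_cows_per_breed Cows per breed (default 9).
#' @param breeds Named list of [breed_params()]
#'   (default [default_breed_params()]).
#' @param pasture_specs Paddock specs (default [default_pasture_specs()]
#'   for the configured breeds).
#' @param days_on_pasture Total grazing days between weighings
#'   (default 70, i.e. 10 weeks).
#' @param track_hours Tracked hours per cow and paddock (default 72,
#'   i.e. 3 days of continuous logging per pasture).
#' @param fix_interval_s GPS fix interval (default 15 s).
#' @param bites_per_bout Recorded bites per observation bout (default 300).
#' @param pedometer_share Fraction of cows per breed wearing a pedometer
#'   (default 2/3: six of nine).
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed, n_cows_per_breed = 9,
                       breeds = default_breed_params(),
                       pasture_specs = NULL,
                       days_on_pasture = 70, track_hours = 72,
                       fix_interval_s = 15, bites_per_bout = 300,
                       pedometer_share = 2 / 3) {
  if (missing(seed) || is.null(seed)) abort_bad_arg("`seed` is mandatory.")
  pasture_specs <- pasture_specs %||% default_pasture_specs(names(breeds))
  structure(
    list(seed = as.integer(seed), n_cows_per_breed = n_cows_per_breed,
         breeds = breeds, pasture_specs = pasture_specs,
         days_on_pasture = days_on_pasture, track_hours = track_hours,
         fix_interval_s = fix_interval_s, bites_per_bout = bites_per_bout,
         pedometer_share = pedometer_share),
    class = "sim_config"
  )
}

#' Simulate a complete grazing study
#'
#' Generates paddocks, cows with claw outlines, GPS tracks, pedometer
#' traces and bite sequences for every cow on every pasture, then realizes
#' end-of-season weights from each cow's mean selected diet quality. The
#' result is a `study_bundle`: the same container the file readers
#' produce, so the whole analysis pipeline runs identically on synthetic
#' and on read-in data.
#'
#' @param config A [sim_config()].
#' @return A `study_bundle` list: `cows`, `claw_outlines`, `gps`,
#'   `pedometer`, `bites`, `taxa` ([taxon_table()]), `paddocks` (named
#'   list), `availability`, `config`.
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  tt <- alpine_taxa()
  seed <- config$seed
  paddocks <- list()
  for (k in seq_along(config$pasture_specs)) {
    sp <- config$pasture_specs[[k]]
    paddocks[[sp$paddock_id]] <- make_pasture(sp, tt, derive_seed(seed, k))
  }
  pasture_ids <- unique(vapply(paddocks, function(p) p$pasture_id,
                               character(1)))
  breeds <- config$breeds
  cows <- list(); outlines <- list()
  for (bi in seq_along(breeds)) {
    sim <- simulate_cows(breeds[[bi]], config$n_cows_per_breed,
                         derive_seed(seed, 100 + bi),
                         days_on_pasture = config$days_on_pasture)
    cows[[bi]] <- sim$cows
    outlines[[bi]] <- sim$outlines
  }
  cows <- bind_rows(cows)
  outlines <- bind_rows(outlines)
  gps <- list(); ped <- list(); bites <- list()
  row <- 0
  for (bi in seq_along(breeds)) {
    bp <- breeds[[bi]]
    bcows <- cows[cows$breed == bp$name, ]
    n_ped <- round(nrow(bcows) * config$pedometer_share)
    for (ci in seq_len(nrow(bcows))) {
      cid <- bcows$cow_id[ci]
      for (pi in seq_along(pasture_ids)) {
        pid <- pasture_ids[pi]
        pad <- paddocks[[paste(pid, bp$name, sep = "-")]]
        row <- row + 1
        tr <- simulate_track(
          pad, bp, derive_seed(seed, 1000 + row),
          duration_h = config$track_hours,
          fix_interval_s = config$fix_interval_s,
          cow_id = cid, t0 = (pi - 1) * 90000
        )
        gps[[row]] <- tr
        if (ci <= n_ped) {
          ped[[row]] <- simulate_pedometer(tr, bp,
                                           derive_seed(seed, 5000 + row))
        }
        bites[[row]] <- simulate_bites(
          pad$availability, tt, pid, bp, config$bites_per_bout,
          derive_seed(seed, 9000 + row), cow_id = cid
        )
      }
    }
  }
  gps <- bind_rows(lapply(gps, function(g) { attr(g, "walk") <- NULL; g }))
  pedometer <- bind_rows(ped)
  bites <- bind_rows(bites)
  # realized diet quality per cow (mean over pastures) -> end weights
  diets <- diet_profiles(bites, tt)
  q_mean <- diets |>
    group_by(.data$cow_id) |>
    summarise(q = mean(.data$quality_score), .groups = "drop")
  q_by_cow <- q_mean$q[match(cows$cow_id, q_mean$cow_id)]
  for (bi in seq_along(breeds)) {
    sel <- cows$breed == breeds[[bi]]$name
    cows$weight_end[sel] <- simulate_weights(
      cows$weight_start[sel], q_by_cow[sel], breeds[[bi]],
      config$days_on_pasture, derive_seed(seed, 200 + bi)
    )
  }
  availability <- purrr::map_dfr(config$pasture_specs, function(sp) {
    tibble(pasture_id = sp$pasture_id, paddock_id = sp$paddock_id,
           taxon_id = sp$availability$taxon_id,
           abundance = sp$availability$abundance)
  }) |> distinct(.data$pasture_id, .data$taxon_id, .keep_all = TRUE) |>
    select(all_of(c("pasture_id", "taxon_id", "abundance")))
  structure(
    list(cows = cows, claw_outlines = outlines, gps = gps,
         pedometer = pedometer, bites = bites, taxa = tt,
         paddocks = paddocks, availability = availability,
         config = config),
    class = "study_bundle"
  )
}

#' @export
print.study_bundle <- function(x, ...) {
  cat(sprintf(
    "<study_bundle: %d cows (%s), %d paddocks, %d GPS fixes, %d bites>\n",
    nrow(x$cows), paste(unique(x$cows$breed), collapse = "/"),
    length(x$paddocks), nrow(x$gps), nrow(x$bites)))
  invisible(x)
}
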