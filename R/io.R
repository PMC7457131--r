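# io_model: file readers/writers, YAML study configuration, and
# cross-validation of a study bundle. CSV dialect: comma-separated, UTF-8,
# mandatory header, decimal point. All coordinates must already be in a
# projected metric CRS; no geodetic transforms are performed.

read_csv_quiet <- function(path) {
  if (!file.exists(path)) abort_bad_arg(sprintf("missing file: %s", path),
                                        class = "grazemetry_validation_error")
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

apply_column_map <- function(df, map) {
  if (is.null(map)) return(df)
  for (canonical in names(map)) {
    from <- map[[canonical]]
    if (from %in% names(df)) names(df)[names(df) == from] <- canonical
  }
  df
}

#' Read GPS fixes from CSV or GPX
#'
#' CSV files need columns `cow_id`, `paddock_id`, `timestamp` (seconds),
#' `x`, `y` (projected metres). GPX tracks are parsed with the convention
#' that `lon`/`lat` attributes already hold projected x/y metres (the
#' package performs no geodetic transforms); cow and paddock ids are taken
#' from the track `<name>` as `cow@paddock`.
#'
#' @param path File path (`.gpx` is detected by extension).
#' @return A tibble `cow_id`, `paddock_id`, `timestamp`, `x`, `y`.
#' @export
read_gps <- function(path) {
  if (grepl("\\.gpx$", path, ignore.case = TRUE)) {
    return(read_gps_gpx(path))
  }
  df <- read_csv_quiet(path)
  check_cols(df, c("cow_id", "paddock_id", "timestamp", "x", "y"), "gps")
  as_tibble(df)
}

read_gps_gpx <- function(path) {
  if (!file.exists(path)) abort_bad_arg(sprintf("missing file: %s", path),
                                        class = "grazemetry_validation_error")
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  out <- purrr::map_dfr(xml2::xml_find_all(doc, ".//trk"), function(trk) {
    nm <- xml2::xml_text(xml2::xml_find_first(trk, "./name"))
    ids <- strsplit(nm, "@", fixed = TRUE)[[1]]
    pts <- xml2::xml_find_all(trk, ".//trkpt")
    times <- xml2::xml_text(xml2::xml_find_all(trk, ".//trkpt/time"))
    tibble(
      cow_id = ids[1],
      paddock_id = if (length(ids) > 1) ids[2] else NA_character_,
      timestamp = as.numeric(as.POSIXct(times, tz = "UTC",
                                        format = "%Y-%m-%dT%H:%M:%OSZ")),
      x = as.numeric(xml2::xml_attr(pts, "lon")),
      y = as.numeric(xml2::xml_attr(pts, "lat"))
    )
  })
  out
}

# parse "x y;x y" water-point text into a matrix
parse_water_points <- function(txt) {
  pts <- strsplit(trimws(strsplit(txt, ";")[[1]]), "\\s+")
  m <- do.call(rbind, lapply(pts, function(p) as.numeric(p[1:2])))
  if (is.null(m) || anyNA(m)) abort_bad_arg("malformed water_points text.")
  m
}

#' Read a study bundle from a YAML configuration
#'
#' The configuration names the input files (paths relative to the config
#' file): `cows`, `claws`, `gps`, `pedometer` (optional), `bites`, `taxa`,
#' `group_members` (optional), `availability`, `paddocks`. An optional
#' `columns:` block maps canonical column names to file-specific ones per
#' table (`columns: {cows: {cow_id: animal}}` reads column `animal` as
#' `cow_id`). The paddock table needs `paddock_id`, `pasture_id`,
#' `area_ha`, `boundary_wkt`, `dem_file` (Esri ASCII), `water_points`
#' (text, `"x y;x y"`).
#'
#' Every record is cross-validated on read: unknown cow, paddock or taxon
#' ids and non-monotone GPS timestamps are errors naming the offending row,
#' never silently dropped.
#'
#' @param config_path Path to the YAML configuration.
#' @return A `study_bundle` (same container [simulate_study()] produces).
#' @export
read_study <- function(config_path) {
  if (!file.exists(config_path)) {
    abort_bad_arg(sprintf("missing config: %s", config_path),
                  class = "grazemetry_validation_error")
  }
  cfg <- yaml::read_yaml(config_path)
  base <- dirname(normalizePath(config_path))
  pth <- function(p) if (is.null(p)) NULL else file.path(base, p)
  cmap <- cfg$columns %||% list()
  rd <- function(key) {
    apply_column_map(read_csv_quiet(pth(cfg[[key]])), cmap[[key]])
  }
  cows <- rd("cows")
  check_cols(cows, c("cow_id", "breed", "weight_start", "weight_end",
                     "days_on_pasture"), "cows")
  claws <- rd("claws")
  check_cols(claws, c("cow_id", "foot", "claw", "vertex_index", "x_cm",
                      "y_cm"), "claws")
  gps <- if (!is.null(cfg$gps)) {
    apply_column_map(read_gps(pth(cfg$gps)), cmap$gps)
  } else NULL
  pedometer <- if (!is.null(cfg$pedometer)) {
    p <- rd("pedometer")
    check_cols(p, c("cow_id", "paddock_id", "duration_s", "steps",
                    "lying_s"), "pedometer")
    p
  } else NULL
  bites <- rd("bites")
  check_cols(bites, c("cow_id", "pasture_id", "sequence_index", "taxon_id"),
             "bites")
  taxa_df <- rd("taxa")
  members <- if (!is.null(cfg$group_members)) rd("group_members") else NULL
  tt <- taxon_table(taxa_df, members)
  availability <- rd("availability")
  check_cols(availability, c("pasture_id", "taxon_id", "abundance"),
             "availability")
  pads_df <- rd("paddocks")
  check_cols(pads_df, c("paddock_id", "pasture_id", "area_ha",
                        "boundary_wkt", "dem_file", "water_points"),
             "paddocks")
  paddocks <- list()
  for (i in seq_len(nrow(pads_df))) {
    paddocks[[pads_df$paddock_id[i]]] <- paddock(
      pads_df$paddock_id[i], pads_df$pasture_id[i],
      pads_df$boundary_wkt[i],
      read_esri_ascii(pth(pads_df$dem_file[i])),
      parse_water_points(pads_df$water_points[i]),
      area_ha = pads_df$area_ha[i]
    )
  }
  bundle <- structure(
    list(cows = as_tibble(cows), claw_outlines = as_tibble(claws),
         gps = if (is.null(gps)) NULL else as_tibble(gps),
         pedometer = if (is.null(pedometer)) NULL else as_tibble(pedometer),
         bites = as_tibble(bites), taxa = tt, paddocks = paddocks,
         availability = as_tibble(availability),
         config = cfg),
    class = "study_bundle"
  )
  validate_bundle(bundle)
  bundle
}

#' Cross-validate a study bundle
#'
#' Referential and ordering checks across all tables: unique cow ids,
#' positive weights, every GPS/pedometer/bite record referencing a known
#' cow and paddock/pasture, known taxa in bites, and strictly increasing
#' GPS timestamps per cow and paddock. The first violation raises a
#' validation error naming the offending row; validation never drops data.
#'
#' @param bundle A `study_bundle`.
#' @return The bundle, invisibly, when valid.
#' @export
validate_bundle <- function(bundle) {
  cows <- bundle$cows
  if (anyDuplicated(cows$cow_id)) {
    abort_bad_arg(sprintf("duplicate cow_id: %s.",
                          cows$cow_id[duplicated(cows$cow_id)][1]),
                  class = "grazemetry_validation_error")
  }
  if (any(cows$weight_start <= 0 | cows$weight_end <= 0)) {
    abort_bad_arg("cow weights must be positive.",
                  class = "grazemetry_validation_error")
  }
  if (any(cows$days_on_pasture < 1)) {
    abort_bad_arg("days_on_pasture must be >= 1.",
                  class = "grazemetry_validation_error")
  }
  known_cows <- cows$cow_id
  known_pads <- names(bundle$paddocks)
  check_ref <- function(df, col, known, what, table) {
    if (is.null(df)) return(invisible())
    bad <- which(!(df[[col]] %in% known))
    if (length(bad)) {
      abort_bad_arg(sprintf("%s row %d references unknown %s '%s'.",
                            table, bad[1], what, df[[col]][bad[1]]),
                    class = "grazemetry_validation_error")
    }
  }
  check_ref(bundle$claw_outlines, "cow_id", known_cows, "cow", "claws")
  check_ref(bundle$gps, "cow_id", known_cows, "cow", "gps")
  check_ref(bundle$gps, "paddock_id", known_pads, "paddock", "gps")
  check_ref(bundle$pedometer, "cow_id", known_cows, "cow", "pedometer")
  check_ref(bundle$pedometer, "paddock_id", known_pads, "paddock", "pedometer")
  check_ref(bundle$bites, "cow_id", known_cows, "cow", "bites")
  pasture_ids <- unique(vapply(bundle$paddocks, function(p) p$pasture_id,
                               character(1)))
  check_ref(bundle$bites, "pasture_id", pasture_ids, "pasture", "bites")
  check_ref(bundle$bites, "taxon_id", bundle$taxa$taxa$taxon_id, "taxon",
            "bites")
  if (!is.null(bundle$gps)) {
    g <- bundle$gps |>
      mutate(.row = dplyr::row_number()) |>
      group_by(.data$cow_id, .data$paddock_id)
    bad <- g |>
      summarise(bad_row = {
        d <- diff(.data$timestamp)
        if (any(d <= 0)) .data$.row[which(d <= 0)[1] + 1] else NA_integer_
      }, .groups = "drop") |>
      filter(!is.na(.data$bad_row))
    if (nrow(bad)) {
      abort_bad_arg(sprintf(
        "gps: non-increasing timestamp for cow '%s' in paddock '%s' (row %d).",
        bad$cow_id[1], bad$paddock_id[1], bad$bad_row[1]),
        class = "grazemetry_validation_error")
    }
  }
  invisible(bundle)
}

#' Write a study bundle to disk
#'
#' Emits exactly the file set [read_study()] consumes (CSV tables, one
#' Esri ASCII DEM per paddock, WKT boundaries inside the paddock table)
#' plus a `study.yaml` configuration, making simulate -> write -> read a
#' lossless round trip.
#'
#' @param bundle A `study_bundle`.
#' @param dir Output directory (created if needed).
#' @return The path of the written YAML config, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name) {
    readr::write_csv(df, file.path(dir, paste0(name, ".csv")))
    paste0(name, ".csv")
  }
  cfg <- list(
    cows = wr(bundle$cows, "cows"),
    claws = wr(bundle$claw_outlines, "claws"),
    bites = wr(bundle$bites, "bites"),
    taxa = wr(bundle$taxa$taxa, "taxa"),
    availability = wr(bundle$availability, "availability")
  )
  if (nrow(bundle$taxa$members)) {
    cfg$group_members <- wr(bundle$taxa$members, "group_members")
  }
  if (!is.null(bundle$gps)) cfg$gps <- wr(bundle$gps, "gps")
  if (!is.null(bundle$pedometer)) cfg$pedometer <- wr(bundle$pedometer,
                                                      "pedometer")
  pads_df <- purrr::map_dfr(bundle$paddocks, function(p) {
    dem_file <- sprintf("dem_%s.asc", p$paddock_id)
    write_esri_ascii(p$dem, file.path(dir, dem_file))
    tibble(
      paddock_id = p$paddock_id, pasture_id = p$pasture_id,
      area_ha = p$area_ha,
      boundary_wkt = format_wkt_polygon(p$boundary),
      dem_file = dem_file,
      water_points = paste(sprintf("%.6g %.6g", p$water[, 1], p$water[, 2]),
                           collapse = ";")
    )
  })
  cfg$paddocks <- wr(pads_df, "paddocks")
  cfg_path <- file.path(dir, "study.yaml")
  yaml::write_yaml(cfg, cfg_path)
  invisible(cfg_path)
}

#' Write result tables with a run manifest
#'
#' One CSV per named table plus a `manifest.json` recording the seed, a
#' hash of the configuration, and the file list, so a rerun with the same
#' seed and configuration is byte-identical and verifiable.
#'
#' @param tables A named list of data frames.
#' @param out_dir Output directory (created if needed).
#' @param seed Seed recorded in the manifest (may be `NULL`).
#' @param config Configuration object hashed into the manifest (may be
#'   `NULL`).
#' @return Invisibly, the manifest as a list.
#' @export
write_results <- function(tables, out_dir, seed = NULL, config = NULL) {
  if (is.null(names(tables)) || any(names(tables) == "")) {
    abort_bad_arg("`tables` must be a fully named list.")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (file.access(out_dir, 2) != 0) {
    abort_bad_arg(sprintf("output directory not writable: %s", out_dir))
  }
  files <- character()
  for (nm in names(tables)) {
    f <- paste0(nm, ".csv")
    readr::write_csv(as.data.frame(tables[[nm]]), file.path(out_dir, f))
    files <- c(files, f)
  }
  manifest <- list(
    package = "grazemetry",
    seed = seed,
    config_hash = if (is.null(config)) NULL else rlang::hash(config),
    tables = as.list(files)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
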