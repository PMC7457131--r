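# foraging module: bite records -> diet composition, Briemle quality
# scoring, Pielou selection evenness, plant-group shares

#' Taxon table with forage-quality indicator values
#'
#' Holds the taxa that can appear in bite records. A taxon is either a
#' plant species with its own Briemle forage-quality indicator value q
#' (1 = worthless to 9 = best forage), or a field-recording group of
#' species that could not be told apart during observation (e.g.
#' broad-leaved Poaceae). A group's effective q is resolved per pasture as
#' the relevee-abundance-weighted mean of its members' values.
#'
#' @param taxa Data frame: `taxon_id`, `kind` (`"species"`/`"group"`),
#'   `quality` (1-9; `NA` for groups), `plant_group` (one of
#'   `broad_grass`, `fine_grass`, `legume`, `thistle`, `shrub`, `other`).
#' @param members Data frame (may be empty if no group taxa):
#'   `group_id`, `member_id`, `pasture_id`, `abundance`; abundances of one
#'   group on one pasture must sum to 1 (tolerance 1e-9) and every
#'   `member_id` must be a species in `taxa`.
#' @return A `taxon_table` object.
#' @export
taxon_table <- function(taxa, members = NULL) {
  check_cols(taxa, c("taxon_id", "kind", "quality", "plant_group"), "taxa")
  if (anyDuplicated(taxa$taxon_id)) {
    abort_bad_arg("duplicate taxon_id in taxon table.",
                  class = "grazemetry_validation_error")
  }
  bad_kind <- setdiff(unique(taxa$kind), c("species", "group"))
  if (length(bad_kind)) abort_bad_arg("taxon kind must be 'species' or 'group'.")
  groups_ok <- c("broad_grass", "fine_grass", "legume", "thistle", "shrub",
                 "other")
  bad_pg <- setdiff(unique(taxa$plant_group), groups_ok)
  if (length(bad_pg)) {
    abort_bad_arg(sprintf("unknown plant_group(s): %s.",
                          paste(bad_pg, collapse = ", ")))
  }
  sp <- taxa[taxa$kind == "species", ]
  if (any(is.na(sp$quality) | sp$quality < 1 | sp$quality > 9)) {
    abort_bad_arg("species quality values must lie in [1, 9].",
                  class = "grazemetry_validation_error")
  }
  members <- members %||% tibble(group_id = character(), member_id = character(),
                                 pasture_id = character(), abundance = numeric())
  check_cols(members, c("group_id", "member_id", "pasture_id", "abundance"),
             "members")
  if (nrow(members)) {
    unknown <- setdiff(members$member_id, sp$taxon_id)
    if (length(unknown)) {
      abort_bad_arg(sprintf("group members are not known species: %s.",
                            paste(unknown, collapse = ", ")),
                    class = "grazemetry_validation_error")
    }
    sums <- members |>
      group_by(.data$group_id, .data$pasture_id) |>
      summarise(s = sum(.data$abundance), .groups = "drop")
    if (any(abs(sums$s - 1) > 1e-9)) {
      bad <- sums[abs(sums$s - 1) > 1e-9, ]
      abort_bad_arg(sprintf(
        "relevee abundances must sum to 1: group %s on pasture %s sums to %.6f.",
        bad$group_id[1], bad$pasture_id[1], bad$s[1]),
        class = "grazemetry_validation_error")
    }
  }
  structure(list(taxa = as_tibble(taxa), members = as_tibble(members)),
            class = "taxon_table")
}

#' @export
print.taxon_table <- function(x, ...) {
  cat(sprintf("<taxon_table: %d taxa (%d species, %d groups)>\n",
              nrow(x$taxa), sum(x$taxa$kind == "species"),
              sum(x$taxa$kind == "group")))
  invisible(x)
}

#' Relative consumption per taxon
#'
#' Reduces a sequence of recorded bites to the share each taxon contributed:
#' count of bites on the taxon over total bites.
#'
#' @param bites Data frame with a `taxon_id` column (one row per recorded
#'   bite); >= 1 row.
#' @return A tibble `taxon_id`, `n_bites`, `proportion` (sums to 1),
#'   sorted by decreasing proportion.
#' @export
relative_consumption <- function(bites) {
  check_cols(bites, "taxon_id", "bites")
  if (nrow(bites) == 0) abort_bad_arg("no bites recorded.",
                                      class = "grazemetry_degenerate_error")
  bites |>
    count(.data$taxon_id, name = "n_bites") |>
    mutate(proportion = .data$n_bites / sum(.data$n_bites)) |>
    arrange(dplyr::desc(.data$proportion), .data$taxon_id)
}

#' Effective forage quality of a species group on one pasture
#'
#' Cover-weighted mean of the member species' Briemle values, with weights
#' from the relevee relative abundances on that pasture.
#'
#' @param tt A [taxon_table()].
#' @param group_id The group taxon id.
#' @param pasture_id The pasture on which to resolve the abundances.
#' @return A single quality value in [1, 9].
#' @export
group_quality <- function(tt, group_id, pasture_id) {
  stopifnot(inherits(tt, "taxon_table"))
  mem <- tt$members |>
    filter(.data$group_id == !!group_id, .data$pasture_id == !!pasture_id)
  if (nrow(mem) == 0) {
    abort_bad_arg(sprintf("no relevee abundances for group '%s' on pasture '%s'.",
                          group_id, pasture_id),
                  class = "grazemetry_validation_error")
  }
  q <- tt$taxa$quality[match(mem$member_id, tt$taxa$taxon_id)]
  sum(mem$abundance * q)
}

# q value for every taxon id on a given pasture (species own value, groups
# resolved through group_quality)
taxon_quality <- function(tt, taxon_ids, pasture_id) {
  idx <- match(taxon_ids, tt$taxa$taxon_id)
  if (anyNA(idx)) {
    abort_bad_arg(sprintf("unknown taxon id(s): %s.",
                          paste(taxon_ids[is.na(idx)], collapse = ", ")),
                  class = "grazemetry_validation_error")
  }
  q <- tt$taxa$quality[idx]
  is_grp <- tt$taxa$kind[idx] == "group"
  if (any(is_grp)) {
    q[is_grp] <- vapply(taxon_ids[is_grp], group_quality, numeric(1),
                        tt = tt, pasture_id = pasture_id)
  }
  q
}

#' Average quality of the consumed forage
#'
#' The Briemle indicator values of the consumed taxa, weighted by their
#' relative consumption: Q = sum p_s q_s. Group taxa are resolved to their
#' pasture-specific cover-weighted quality first.
#'
#' @param consumption A tibble as from [relative_consumption()]
#'   (`taxon_id`, `proportion`).
#' @param tt A [taxon_table()].
#' @param pasture_id Pasture on which group qualities are resolved.
#' @return A single value on the 1-9 indicator scale.
#' @export
diet_quality <- function(consumption, tt, pasture_id) {
  check_cols(consumption, c("taxon_id", "proportion"), "consumption")
  q <- taxon_quality(tt, consumption$taxon_id, pasture_id)
  sum(consumption$proportion * q)
}

#' Evenness of forage selection
#'
#' Pielou's J of the diet proportions over the taxa actually consumed
#' (p > 0); see [pielou_evenness()]. A single-taxon diet has no defined
#' evenness and returns `NA` flagged with attribute `undefined`.
#'
#' @param consumption A tibble with a `proportion` column.
#' @return Evenness in (0, 1] or flagged `NA`.
#' @export
selection_evenness <- function(consumption) {
  check_cols(consumption, "proportion", "consumption")
  pielou_evenness(consumption$proportion)
}

#' Diet share per plant group
#'
#' Sums relative consumption within the coarse plant groups (broad-leaved
#' grasses, fine-leaved grasses, legumes, thistles, shrubs, other).
#'
#' @param consumption A tibble (`taxon_id`, `proportion`).
#' @param tt A [taxon_table()].
#' @return A tibble `plant_group`, `share`, with every group present
#'   (zero share when unconsumed); shares sum to 1.
#' @export
group_shares <- function(consumption, tt) {
  check_cols(consumption, c("taxon_id", "proportion"), "consumption")
  idx <- match(consumption$taxon_id, tt$taxa$taxon_id)
  if (anyNA(idx)) {
    abort_bad_arg(sprintf("unknown taxon id(s): %s.",
                          paste(consumption$taxon_id[is.na(idx)], collapse = ", ")),
                  class = "grazemetry_validation_error")
  }
  groups <- c("broad_grass", "fine_grass", "legume", "thistle", "shrub", "other")
  pg <- tt$taxa$plant_group[idx]
  share <- vapply(groups, function(g) sum(consumption$proportion[pg == g]),
                  numeric(1))
  tibble(plant_group = groups, share = unname(share))
}

#' Per-cow diet profiles
#'
#' Reduces all bite records to one row per cow x pasture: taxon proportions
#' (nested), forage quality score Q, Pielou selection evenness J, and the
#' plant-group shares as columns `share_<group>`.
#'
#' @param bites Data frame: `cow_id`, `pasture_id`, `sequence_index`,
#'   `taxon_id`.
#' @param tt A [taxon_table()].
#' @return A tibble, one row per cow x pasture, with columns `n_bites`,
#'   `n_taxa`, `quality_score`, `selection_evenness`, `evenness_defined`
#'   and the six `share_*` columns.
#' @export
diet_profiles <- function(bites, tt) {
  check_cols(bites, c("cow_id", "pasture_id", "taxon_id"), "bites")
  unknown <- setdiff(unique(bites$taxon_id), tt$taxa$taxon_id)
  if (length(unknown)) {
    abort_bad_arg(sprintf("bite records reference unknown taxa: %s.",
                          paste(unknown, collapse = ", ")),
                  class = "grazemetry_validation_error")
  }
  bites |>
    group_by(.data$cow_id, .data$pasture_id) |>
    dplyr::group_modify(function(df, key) {
      cons <- relative_consumption(df)
      ev <- selection_evenness(cons)
      gs <- group_shares(cons, tt)
      wide <- setNames(as.list(gs$share), paste0("share_", gs$plant_group))
      dplyr::bind_cols(
        tibble(
          n_bites = sum(cons$n_bites),
          n_taxa = nrow(cons),
          quality_score = diet_quality(cons, tt, key$pasture_id),
          selection_evenness = as.numeric(ev),
          evenness_defined = !isTRUE(attr(ev, "undefined"))
        ),
        as_tibble(wide)
      )
    }) |>
    ungroup()
}

#' Maximum-likelihood diet-selectivity estimate
#'
#' Fits the softmax selectivity temperature tau of the diet-choice model
#' p_s proportional to a_s * exp(tau * q_s) (a_s availability, q_s Briemle
#' quality) to observed bite counts by profile maximum likelihood. tau = 0
#' is neutral (availability-only) foraging; large tau means strict
#' selection for quality.
#'
#' @param counts Observed bites per taxon (same order as `availability`).
#' @param availability Relative availability per taxon (sums to 1).
#' @param quality Briemle quality per taxon.
#' @param interval Search interval for tau.
#' @return A one-row tibble: `tau`, `logLik`, `n_bites`.
#' @export
estimate_selectivity <- function(counts, availability, quality,
                                 interval = c(-2, 8)) {
  stopifnot(length(counts) == length(availability),
            length(counts) == length(quality))
  if (sum(counts) == 0) abort_bad_arg("no bites observed.")
  nll <- function(tau) {
    w <- availability * exp(tau * quality)
    p <- w / sum(w)
    -sum(counts[counts > 0] * log(p[counts > 0]))
  }
  opt <- optimize(nll, interval = interval)
  tibble(tau = opt$minimum, logLik = -opt$objective, n_bites = sum(counts))
}
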