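test_that("taxon table validates qualities and relevee abundances", {
  tt <- tiny_taxa()
  expect_s3_class(tt, "taxon_table")
  bad_q <- tibble::tibble(taxon_id = "x", kind = "species", quality = 11,
                          plant_group = "other")
  expect_error(taxon_table(bad_q), "\\[1, 9\\]")
  bad_sum <- tibble::tibble(group_id = "grass_group", member_id = "grass_a",
                            pasture_id = "P1", abundance = 0.9)
  taxa <- tt$taxa
  expect_error(taxon_table(taxa, bad_sum), "sum to 1")
})

test_that("relative consumption is the bite-count share, order-invariant", {
  bites <- tibble::tibble(taxon_id = c(rep("good_grass", 50),
                                       rep("poor_shrub", 50)))
  rc <- relative_consumption(bites)
  expect_equal(sort(rc$proportion), c(0.5, 0.5))
  expect_equal(sum(rc$proportion), 1)
  one <- relative_consumption(tibble::tibble(taxon_id = rep("good_grass", 9)))
  expect_equal(one$proportion, 1)
  set.seed(5)
  shuffled <- bites[sample(nrow(bites)), , drop = FALSE]
  expect_equal(relative_consumption(shuffled), rc)
  expect_error(relative_consumption(tibble::tibble(taxon_id = character(0))),
               "no bites")
})

test_that("group quality is the cover-weighted mean of member values", {
  tt <- tiny_taxa()
  # members q = 8 (a = 0.75) and q = 6 (a = 0.25) -> 7.5
  expect_equal(group_quality(tt, "grass_group", "P1"), 7.5)
  expect_error(group_quality(tt, "grass_group", "P9"), "P9")
})

test_that("diet quality is the consumption-weighted Briemle score", {
  tt <- tiny_taxa()
  cons <- tibble::tibble(taxon_id = c("good_grass", "poor_shrub"),
                         proportion = c(0.5, 0.5))
  expect_equal(diet_quality(cons, tt, "P1"), 5)
  single <- tibble::tibble(taxon_id = "good_grass", proportion = 1)
  expect_equal(diet_quality(single, tt, "P1"), 8)
  # resolves group taxa through the pasture relevees
  grp <- tibble::tibble(taxon_id = c("grass_group", "poor_shrub"),
                        proportion = c(0.4, 0.6))
  expect_equal(diet_quality(grp, tt, "P1"), 0.4 * 7.5 + 0.6 * 2)
  # bounded by the consumed qualities (convexity), random proportions
  set.seed(6)
  for (i in 1:10) {
    p <- runif(2); p <- p / sum(p)
    q <- diet_quality(tibble::tibble(taxon_id = c("good_grass", "thistle_sp"),
                                     proportion = p), tt, "P1")
    expect_gte(q, 2); expect_lte(q, 8)
  }
})

test_that("diet quality is invariant to splitting a taxon of equal quality", {
  tt <- tiny_taxa()
  merged <- tibble::tibble(taxon_id = c("good_grass", "poor_shrub"),
                           proportion = c(0.6, 0.4))
  # grass_a has the same q = 8 as good_grass: split 0.6 into 0.35 + 0.25
  split <- tibble::tibble(taxon_id = c("good_grass", "grass_a", "poor_shrub"),
                          proportion = c(0.35, 0.25, 0.4))
  expect_equal(diet_quality(split, tt, "P1"), diet_quality(merged, tt, "P1"))
})

test_that("selection evenness flags single-taxon diets", {
  j <- selection_evenness(tibble::tibble(proportion = 1))
  expect_true(is.na(j))
  expect_true(attr(j, "undefined"))
  expect_equal(selection_evenness(tibble::tibble(proportion = c(0.75, 0.25))),
               0.8113, tolerance = 1e-4)
})

test_that("group shares partition the diet", {
  tt <- tiny_taxa()
  cons <- tibble::tibble(taxon_id = c("thistle_sp", "good_grass"),
                         proportion = c(0.3, 0.7))
  gs <- group_shares(cons, tt)
  expect_equal(gs$share[gs$plant_group == "thistle"], 0.3)
  expect_equal(gs$share[gs$plant_group == "shrub"], 0)
  expect_equal(sum(gs$share), 1)
})

test_that("diet_profiles reduces bite records per cow and pasture", {
  tt <- tiny_taxa()
  bites <- tibble::tibble(
    cow_id = rep(c("c1", "c2"), each = 40),
    pasture_id = "P1",
    sequence_index = rep(1:40, 2),
    taxon_id = c(rep(c("good_grass", "poor_shrub"), 20),
                 rep("thistle_sp", 40))
  )
  prof <- diet_profiles(bites, tt)
  expect_equal(nrow(prof), 2)
  c1 <- prof[prof$cow_id == "c1", ]
  expect_equal(c1$quality_score, 5)
  expect_equal(c1$selection_evenness, 1)
  c2 <- prof[prof$cow_id == "c2", ]
  expect_false(c2$evenness_defined)
  expect_equal(c2$share_thistle, 1)
  unknown <- dplyr::mutate(bites, taxon_id = "martian_moss")
  expect_error(diet_profiles(unknown, tt), "martian_moss")
})

test_that("selectivity temperature is recoverable from bite counts", {
  tt <- tiny_taxa()
  av <- tibble::tibble(taxon_id = c("good_grass", "grass_b", "poor_shrub",
                                    "thistle_sp"),
                       abundance = c(0.2, 0.3, 0.3, 0.2))
  q <- c(8, 6, 2, 2)
  # neutral foraging estimates tau ~ 0
  set.seed(9)
  w0 <- av$abundance
  counts0 <- as.vector(table(factor(sample(1:4, 4000, TRUE, w0), levels = 1:4)))
  est0 <- estimate_selectivity(counts0, av$abundance, q)
  expect_lt(abs(est0$tau), 0.05)
})
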