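cfg <- cnl_config()

test_that("component points follow the strictly-greater step convention", {
  pt <- cfg$point_tables
  for (tab in pt) expect_identical(component_points(0, tab), 0L)
  # boundary: points switch strictly above the threshold
  expect_identical(component_points(335, pt$energy), 0L)
  expect_identical(component_points(335.01, pt$energy), 1L)
  # saturation beyond the last threshold
  expect_identical(component_points(10000, pt$energy), 10L)
  expect_identical(component_points(100, pt$fvln), 5L)
  expect_identical(component_points(60, pt$fvln), 1L)  # 60 not > 60
  expect_identical(component_points(61, pt$fvln), 2L)
  expect_error(component_points(-1, pt$energy), "non-negative")
  expect_error(component_points(Inf, pt$energy), "finite")
  # non-decreasing in the value
  vals <- seq(0, 4000, by = 37)
  pts <- vapply(vals, component_points, integer(1), tab = pt$energy)
  expect_true(all(diff(pts) >= 0))
})

test_that("score extremes and the protein gate behave as specified", {
  zero <- make_food("z")
  expect_identical(fsa_score(zero, cfg)$total, 0L)

  worst <- make_food("w", energy_kj = 4000, sugars_g = 50, saturates_g = 12,
                     sodium_mg = 1000, lipid_g = 30)
  expect_identical(fsa_score(worst, cfg)$total, 40L)

  best <- make_food("b", fvln_percent = 100, fibre_g = 10, protein_g = 10)
  expect_identical(fsa_score(best, cfg)$total, -15L)

  # protein gate: A >= 11 and fvln points < 5 withholds protein points...
  gated <- make_food("g", energy_kj = 2000, saturates_g = 6, sodium_mg = 500,
                     lipid_g = 10, protein_g = 10)
  s <- fsa_score(gated, cfg)
  expect_gte(s$a_points, 11)
  expect_false(s$protein_counted)
  expect_identical(s$total, s$a_points - 0L)
  # ...unless the food is a cheese
  cheese <- make_food("c", category = "cheese", energy_kj = 2000,
                      saturates_g = 6, sodium_mg = 500, lipid_g = 10,
                      protein_g = 10)
  sc <- fsa_score(cheese, cfg)
  expect_true(sc$protein_counted)
  expect_identical(sc$total, sc$a_points - 5L)
  # ...or fvln points reach 5
  fv <- make_food("f", energy_kj = 2000, saturates_g = 6, sodium_mg = 500,
                  lipid_g = 10, protein_g = 10, fvln_percent = 90)
  expect_true(fsa_score(fv, cfg)$protein_counted)

  expect_error(fsa_score(list(energy_kj = 1), cfg), "sugars_g")
})

test_that("category adaptations reroute components to their own tables", {
  # beverages score energy and sugars on the steeper beverage tables
  bev <- make_food("bev", category = "beverage", energy_kj = 200,
                   sugars_g = 9, carb_g = 11)
  s <- fsa_score(bev, cfg)
  expect_identical(unname(s$components["energy"]), 6L)   # 200 kJ > 180
  expect_identical(unname(s$components["sugars"]), 5L)   # 9 g > 7.5
  food_like <- make_food("fl", energy_kj = 200, sugars_g = 9, carb_g = 11)
  sf <- fsa_score(food_like, cfg)
  expect_identical(unname(sf$components["energy"]), 0L)
  expect_identical(unname(sf$components["sugars"]), 1L)

  # added fats score the saturates/lipids ratio instead of saturates
  fat <- make_food("fat", category = "added_fat", lipid_g = 80,
                   saturates_g = 40)
  expect_identical(unname(fsa_score(fat, cfg)$components["saturates"]),
                   7L)  # ratio 50% > 46
  plain <- make_food("pl", lipid_g = 80, saturates_g = 40)
  expect_identical(unname(fsa_score(plain, cfg)$components["saturates"]),
                   10L)
})

test_that("colour class boundaries sit exactly at the printed cut-offs", {
  food_expect <- c("-15" = "GREEN", "-1" = "GREEN", "0" = "YELLOW",
                   "2" = "YELLOW", "3" = "ORANGE", "10" = "ORANGE",
                   "11" = "PINK", "18" = "PINK", "19" = "RED",
                   "40" = "RED")
  for (sc in names(food_expect)) {
    expect_identical(allocate_class(as.numeric(sc), "general_food"),
                     unname(food_expect[sc]), label = paste("food score", sc))
  }
  bev_expect <- c("-15" = "YELLOW", "1" = "YELLOW", "2" = "ORANGE",
                  "5" = "ORANGE", "6" = "PINK", "9" = "PINK", "10" = "RED")
  for (sc in names(bev_expect)) {
    expect_identical(allocate_class(as.numeric(sc), "beverage"),
                     unname(bev_expect[sc]),
                     label = paste("beverage score", sc))
  }
  # Green is reserved for plain water / unsweetened hot beverages
  expect_identical(allocate_class(10, "beverage", is_plain_water = TRUE),
                   "GREEN")
  expect_identical(
    allocate_class(0, "beverage", is_unsweetened_hot_beverage = TRUE),
    "GREEN")
  expect_error(allocate_class(41, "general_food"), "range")
  expect_error(allocate_class(-16, "general_food"), "range")
  # every score maps to exactly one class on both scales
  for (sc in -15:40) {
    expect_length(allocate_class(sc, "general_food"), 1)
    expect_length(allocate_class(sc, "beverage"), 1)
  }
})

test_that("score is monotone in each component's direction", {
  set.seed(42)
  a_fields <- c("energy_kj", "sugars_g", "saturates_g", "sodium_mg")
  c_fields <- c("fvln_percent", "fibre_g", "protein_g")
  for (i in 1:40) {
    base <- random_composition()
    t0 <- fsa_score(base, cfg)$total
    for (f in a_fields) {
      up <- base
      up[[f]] <- up[[f]] * 1.5
      if (f == "saturates_g") up$lipid_g <- max(up$lipid_g, up[[f]])
      expect_gte(fsa_score(up, cfg)$total, t0)
    }
    for (f in c_fields) {
      up <- base
      up[[f]] <- min(if (f == "fvln_percent") 100 else Inf, up[[f]] * 1.5)
      expect_lte(fsa_score(up, cfg)$total, t0)
    }
  }
})

test_that("scorer agrees with an independent step-table oracle", {
  set.seed(7)
  cats <- c("general_food", "beverage", "cheese", "added_fat")
  for (i in 1:400) {
    comp <- random_composition(sample(cats, 1))
    expect_identical(fsa_score(comp, cfg)$total, as.integer(oracle_fsa(comp)),
                     label = paste("composition", i, comp$category))
  }
})

test_that("brute-force enumeration confirms the -15..40 scale", {
  rng <- enumerate_score_range(cfg)
  expect_identical(rng$min, -15L)
  expect_identical(rng$max, 40L)
  expect_gt(rng$n_combinations, 1e6)
  # the extremes are achievable by concrete compositions
  expect_identical(
    fsa_score(make_food("x", fvln_percent = 100, fibre_g = 10,
                        protein_g = 10), cfg)$total, -15L)
  expect_identical(
    fsa_score(make_food("y", energy_kj = 4000, sugars_g = 50,
                        saturates_g = 12, sodium_mg = 1000,
                        lipid_g = 30), cfg)$total, 40L)
})
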