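cfg <- cnl_config()

toy_foods <- function() {
  score_foods(dplyr::bind_rows(
    make_food("green", fvln_percent = 100, fibre_g = 5, carb_g = 10),
    make_food("red", energy_kj = 4000, sugars_g = 50, saturates_g = 12,
              sodium_mg = 1000, lipid_g = 30, carb_g = 60, protein_g = 5),
    make_food("wine", category = "beverage", is_alcoholic = TRUE,
              alcohol_g = 10, carb_g = 2)
  ), cfg)
}

test_that("day weighting reproduces the 5/7 + 2/7 rule", {
  foods <- toy_foods()
  # identical intake on all three days is a fixed point
  rec <- dplyr::bind_rows(
    make_records("p", "green", 200, record_index = 1L),
    make_records("p", "green", 200, record_index = 2L),
    make_records("p", "green", 200, record_index = 3L,
                 day_type = "weekend"))
  d <- weighted_daily_intake(rec, foods, cfg)
  expect_equal(d$food_quantities$qty_g_day, 200)

  # 700 / 700 kcal weekdays + 1400 kcal weekend -> 900 kcal/day
  # (the green toy food has 40 kcal/100 g)
  q <- c(700, 700, 1400) / 40 * 100
  rec2 <- dplyr::bind_rows(
    make_records("p", "green", q[1], record_index = 1L),
    make_records("p", "green", q[2], record_index = 2L),
    make_records("p", "green", q[3], record_index = 3L,
                 day_type = "weekend"))
  d2 <- weighted_daily_intake(rec2, foods, cfg)
  expect_equal(d2$nutrients$energy_kcal, 5 / 7 * 700 + 2 / 7 * 1400)

  # an empty (declared) weekend record contributes zero
  meta <- tibble::tibble(person_id = "p", record_index = 1:3,
                         day_type = c("weekday", "weekday", "weekend"))
  rec3 <- rec2[rec2$record_index != 3, ]
  d3 <- weighted_daily_intake(rec3, foods, cfg, record_meta = meta)
  expect_equal(d3$nutrients$energy_kcal, 5 / 7 * 700)

  # non-standard mixes error under strict, re-weight generically otherwise
  rec4 <- dplyr::bind_rows(
    make_records("p", "green", q[1], record_index = 1L),
    make_records("p", "green", q[2], record_index = 2L),
    make_records("p", "green", q[3], record_index = 3L))
  expect_error(weighted_daily_intake(rec4, foods, cfg), "record mix")
  d4 <- weighted_daily_intake(rec4, foods, cfg, strict = FALSE)
  expect_equal(d4$nutrients$energy_kcal, mean(c(700, 700, 1400)))

  expect_error(
    weighted_daily_intake(make_records("p", "nope", 10), foods, cfg,
                          strict = FALSE), "unknown food")
})

test_that("Schofield BMR matches the band coefficients", {
  expect_equal(schofield_bmr("male", 30, 70, cfg), 11.472 * 70 + 873.1)
  expect_equal(schofield_bmr("female", 25, 60, cfg), 14.818 * 60 + 486.6)
  expect_equal(schofield_bmr("male", 65, 80, cfg), 11.711 * 80 + 587.7)
  # strictly increasing in weight, deterministic
  expect_gt(schofield_bmr("female", 40, 75, cfg),
            schofield_bmr("female", 40, 60, cfg))
  expect_identical(schofield_bmr("male", 50, 82, cfg),
                   schofield_bmr("male", 50, 82, cfg))
  expect_error(schofield_bmr("male", 12, 40, cfg), "adults")
})

test_that("Goldberg cut-off matches its closed form and orders correctly", {
  g <- cfg$goldberg
  s <- sqrt(g$cv_within_ei^2 / g$days + g$cv_bmr^2 + g$cv_pal^2)
  expect_equal(goldberg_cutoff(1.55, cfg),
               1.55 * exp(-qnorm(0.975) * s / 100))
  # the canonical 3-day individual cut-off sits near 1.0
  expect_equal(goldberg_cutoff(1.55, cfg), 1.01, tolerance = 0.01)

  expect_false(goldberg_underreporter(2.0 * 1500, 1500, pal = 1.55, cfg))
  expect_true(goldberg_underreporter(0, 1500, pal = 1.55, cfg))
  expect_error(goldberg_underreporter(2000, -1, pal = 1.55, cfg))

  # larger within-subject CV -> lower cut-off -> never more exclusions
  cuts <- vapply(c(10, 23, 35, 50), function(cv) {
    goldberg_cutoff(1.55, cnl_config(goldberg = list(cv_within_ei = cv)))
  }, numeric(1))
  expect_true(all(diff(cuts) < 0))
  ratios <- seq(0.5, 2, by = 0.01)
  excl <- vapply(cuts, function(ct) sum(ratios < ct), numeric(1))
  expect_true(all(diff(excl) <= 0))
})

test_that("colour shares form a composition and exclude alcohol", {
  foods <- toy_foods()
  rec <- dplyr::bind_rows(
    make_records("p", "green", 100, record_index = 1L),
    make_records("p", "green", 100, record_index = 2L),
    make_records("p", "green", 100, record_index = 3L,
                 day_type = "weekend"))
  s <- colour_energy_shares(compute_daily_intakes(rec, foods, cfg))
  expect_equal(unlist(s[1, -1]), c(green = 100, yellow = 0, orange = 0,
                                   pink = 0, red = 0))

  # 300 kcal GREEN + 100 kcal RED + 200 kcal alcohol -> (75, 0, 0, 0, 25)
  # toy energies: green 40, red 355, wine 78 kcal/100 g
  f <- toy_foods()
  e <- setNames(f$energy_kcal, f$food_id)
  one_day <- function(i, dt = "weekday") {
    make_records("p", c("green", "red", "wine"),
                 100 * c(300 / e[["green"]], 100 / e[["red"]],
                         200 / e[["wine"]]),
                 record_index = i, day_type = dt)
  }
  rec2 <- dplyr::bind_rows(one_day(1L), one_day(2L), one_day(3L, "weekend"))
  s2 <- colour_energy_shares(compute_daily_intakes(rec2, f, cfg))
  expect_equal(unlist(s2[1, -1]),
               c(green = 75, yellow = 0, orange = 0, pink = 0, red = 25))

  # shares always sum to 100 on generated data
  pop <- shared_pop()
  sh <- colour_energy_shares(pop$diets$baseline)
  expect_equal(rowSums(sh[, -1]), rep(100, nrow(sh)), tolerance = 1e-9)
  expect_true(all(as.matrix(sh[, -1]) >= 0))

  # zero non-alcohol energy is undefined
  rec3 <- dplyr::bind_rows(
    make_records("p", "wine", 100, record_index = 1L),
    make_records("p", "wine", 100, record_index = 2L),
    make_records("p", "wine", 100, record_index = 3L,
                 day_type = "weekend"))
  expect_error(colour_energy_shares(compute_daily_intakes(rec3, f, cfg)),
               "zero non-alcohol")
})

test_that("screening joins intakes, expenditure and the Goldberg flag", {
  pop <- shared_pop()
  scr <- pop$screen
  expect_true(all(c("bmr", "expenditure", "under_reporter") %in% names(scr)))
  expect_equal(scr$expenditure, scr$bmr * scr$pal_multiplier)
  # flags recover exactly the planted under-reporters at the fixture seed
  truth <- pop$raw$truth
  expect_identical(scr$under_reporter[match(truth$person_id, scr$person_id)],
                   truth$under_reporter)
})
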