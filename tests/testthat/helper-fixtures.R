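# Shared fixtures and independent oracles for the suite. Everything is
# built in code; the medium synthetic population is generated once per
# session and cached.

# one fully-specified food row; nutrient defaults are all zero
make_food <- function(food_id, group_id = "g1", category = "general_food",
                      energy_kcal = NULL, energy_kj = NULL, protein_g = 0,
                      carb_g = 0, sugars_g = 0, added_sugars_g = 0,
                      lipid_g = 0, saturates_g = 0, fibre_g = 0,
                      sodium_mg = 0, fvln_percent = 0, alcohol_g = 0,
                      is_plain_water = FALSE,
                      is_unsweetened_hot_beverage = FALSE,
                      is_alcoholic = FALSE) {
  if (is.null(energy_kcal)) {
    energy_kcal <- 4 * (carb_g + protein_g) + 9 * lipid_g + 7 * alcohol_g
  }
  if (is.null(energy_kj)) energy_kj <- energy_kcal * 4.184
  tibble::tibble(
    food_id = food_id, name = food_id, group_id = group_id,
    category = category, energy_kcal = energy_kcal, energy_kj = energy_kj,
    protein_g = protein_g, carb_g = carb_g, sugars_g = sugars_g,
    added_sugars_g = added_sugars_g, lipid_g = lipid_g,
    saturates_g = saturates_g, fibre_g = fibre_g, sodium_mg = sodium_mg,
    fvln_percent = fvln_percent, alcohol_g = alcohol_g,
    is_plain_water = is_plain_water,
    is_unsweetened_hot_beverage = is_unsweetened_hot_beverage,
    is_alcoholic = is_alcoholic)
}

make_records <- function(person_id, food_ids, quantities,
                         record_index = 1L, day_type = "weekday") {
  tibble::tibble(person_id = person_id, record_index = record_index,
                 day_type = day_type, food_id = food_ids,
                 quantity_g = quantities)
}

# --- independent scoring oracle ------------------------------------------
# A table lookup built on stats::stepfun (right-continuous steps placed so
# that points switch just above each threshold), entirely separate from
# the package's which()/max() code path.
oracle_points <- function(value, tab) {
  f <- stats::stepfun(tab$thresholds, c(0, tab$points), right = TRUE)
  as.integer(f(value))
}

oracle_fsa <- function(food, config = cnlsim::cnl_config()) {
  pt <- config$point_tables
  cat_ <- food$category
  e_tab <- if (cat_ == "beverage") pt$energy_beverage else pt$energy
  s_tab <- if (cat_ == "beverage") pt$sugars_beverage else pt$sugars
  a <- oracle_points(food$energy_kj, e_tab) +
    oracle_points(food$sugars_g, s_tab) +
    (if (cat_ == "added_fat") {
      r <- if (food$lipid_g > 0) 100 * food$saturates_g / food$lipid_g else 0
      oracle_points(r, pt$sat_lipid_ratio)
    } else {
      oracle_points(food$saturates_g, pt$saturates)
    }) +
    oracle_points(food$sodium_mg, pt$sodium)
  p_fvln <- oracle_points(food$fvln_percent, pt$fvln)
  p_fib <- oracle_points(food$fibre_g, pt$fibre)
  p_pro <- oracle_points(food$protein_g, pt$protein)
  protein_in <- a < 11 || p_fvln >= 5 || cat_ == "cheese"
  a - (p_fvln + p_fib + if (protein_in) p_pro else 0L)
}

# random composition generator for oracle-equivalence checks
random_composition <- function(category = "general_food") {
  list(energy_kj = stats::runif(1, 0, 4000),
       sugars_g = stats::runif(1, 0, 60),
       saturates_g = stats::runif(1, 0, 15),
       sodium_mg = stats::runif(1, 0, 1200),
       fvln_percent = stats::runif(1, 0, 100),
       fibre_g = stats::runif(1, 0, 6),
       protein_g = stats::runif(1, 0, 12),
       lipid_g = stats::runif(1, 15, 40),
       category = category)
}

# --- cached medium synthetic population -----------------------------------
# Built once per test session: scored food table, population of 400 with
# under-reporters dropped, baseline diets and the three scenario results.
.fixture_env <- new.env(parent = emptyenv())

shared_pop <- function() {
  if (!is.null(.fixture_env$pop)) return(.fixture_env$pop)
  foods <- cnlsim::generate_food_table(seed = 7)
  pop <- cnlsim::generate_population(400, foods, seed = 11)
  d0 <- cnlsim::compute_daily_intakes(pop$records, foods)
  screen <- cnlsim::screen_underreporters(d0, pop$persons)
  kept <- screen$person_id[!screen$under_reporter]
  records <- pop$records[pop$records$person_id %in% kept, ]
  baseline <- cnlsim::compute_daily_intakes(records, foods)
  scen <- list(S1 = cnlsim::apply_scenario1(records, foods),
               S2 = cnlsim::apply_scenario2(records, foods),
               S3 = cnlsim::apply_scenario3(records, foods, 0.30, seed = 5))
  diets <- c(list(baseline = baseline),
             lapply(scen, cnlsim::recompute_intakes))
  .fixture_env$pop <- list(foods = foods, raw = pop, screen = screen,
                           records = records, scenarios = scen,
                           diets = diets)
  .fixture_env$pop
}

# large population at the cluster-recovery study conditions (n = 2000),
# cached likewise
shared_big <- function() {
  if (!is.null(.fixture_env$big)) return(.fixture_env$big)
  foods <- cnlsim::generate_food_table(seed = 7)
  pop <- cnlsim::generate_population(2000, foods, seed = 17)
  diets <- cnlsim::compute_daily_intakes(pop$records, foods)
  screen <- cnlsim::screen_underreporters(diets, pop$persons)
  kept <- screen$person_id[!screen$under_reporter]
  shares <- cnlsim::colour_energy_shares(
    cnlsim::compute_daily_intakes(
      pop$records[pop$records$person_id %in% kept, ], foods))
  .fixture_env$big <- list(foods = foods, raw = pop, screen = screen,
                           shares = shares)
  .fixture_env$big
}

# total grams consumed per person in an event table
grams_per_person <- function(records) {
  out <- tapply(records$quantity_g, records$person_id, sum)
  out[order(names(out))]
}
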