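#' Default food-group taxonomy for the synthetic food table
#'
#' Food groups of similar culinary use, at a moderate level of
#' aggregation, each mapped to a composition archetype and a scoring
#' category. Beverage groups sit on the beverage class scale; the
#' alcoholic group is flagged and excluded from colour shares and
#' substitution downstream.
#'
#' @return Tibble with `group_id`, `archetype`, `category` and flags.
#' @export
default_food_groups <- function() {
  tibble::tribble(
    ~group_id,            ~archetype,     ~category,         ~base_weight,
    "fruits",             "fruit_veg",    "general_food",    2.0,
    "vegetables",         "fruit_veg",    "general_food",    2.5,
    "bread_pasta_rice",   "starch",       "general_food",    2.5,
    "whole_grains",       "wholegrain",   "general_food",    0.8,
    "breakfast_cereals",  "cereal",       "general_food",    0.5,
    "potatoes",           "starch",       "general_food",    1.2,
    "legumes",            "legume",       "general_food",    0.6,
    "meat",               "meat",         "general_food",    2.0,
    "fish",               "fish",         "general_food",    1.0,
    "processed_meat",     "processed",    "general_food",    1.0,
    "eggs",               "egg",          "general_food",    0.8,
    "dairy_desserts",     "dairy_sweet",  "general_food",    1.0,
    "cheese",             "cheese",       "cheese",          1.8,
    "milk",               "milk",         "general_food",    1.2,
    "yogurt",             "dairy_plain",  "general_food",    1.5,
    "fats",               "fat",          "added_fat",       5.0,
    "biscuits_cakes",     "sweet_baked",  "general_food",    1.2,
    "pastries",           "sweet_baked",  "general_food",    0.8,
    "confectionery",      "sweet",        "general_food",    0.8,
    "salty_snacks",       "snack",        "general_food",    0.6,
    "dried_fruits",       "dried_fruit",  "dried_fruit_nut", 0.3,
    "soft_drinks",        "sweet_drink",  "beverage",        1.0,
    "juices",             "juice",        "beverage",        1.0,
    "waters",             "water",        "beverage",        1.0,
    "hot_beverages",      "hot_bev",      "beverage",        1.0,
    "alcoholic_beverages", "alcohol",     "beverage",        1.0
  )
}

# internal: archetype composition endpoints per 100 g. Each archetype has
# a "healthy" and an "unhealthy" pole; a food is drawn by interpolating
# between the poles (intensity tied to its target colour class) with
# multiplicative noise. sat/sugar/added are fractions of lipid/carb/sugar.
.archetypes <- list(
  fruit_veg  = list(h = c(pr = 1.2, li = 0.3, sf = .20, cb = 8,  su = .70, ad = 0,   fi = 3.2, na = 10,   fv = 100, al = 0),
                    u = c(pr = 1.5, li = 9,   sf = .45, cb = 22, su = .80, ad = .55, fi = 1.0, na = 620,  fv = 42,  al = 0)),
  starch     = list(h = c(pr = 4,  li = 2.5, sf = .30, cb = 26, su = .04, ad = 0,   fi = 3.2, na = 120,  fv = 0,   al = 0),
                    u = c(pr = 7,  li = 13,  sf = .40, cb = 50, su = .15, ad = .50, fi = 1.2, na = 680,  fv = 0,   al = 0)),
  wholegrain = list(h = c(pr = 8,  li = 3.5, sf = .18, cb = 58, su = .03, ad = 0,   fi = 8,   na = 10,   fv = 0,   al = 0),
                    u = c(pr = 8,  li = 7,   sf = .35, cb = 66, su = .20, ad = .80, fi = 3.5, na = 450,  fv = 0,   al = 0)),
  cereal     = list(h = c(pr = 10, li = 3,   sf = .22, cb = 58, su = .10, ad = .60, fi = 7.5, na = 40,   fv = 0,   al = 0),
                    u = c(pr = 6,  li = 14,  sf = .50, cb = 76, su = .45, ad = .95, fi = 2,   na = 520,  fv = 0,   al = 0)),
  legume     = list(h = c(pr = 8,  li = 2.2, sf = .18, cb = 14, su = .04, ad = 0,   fi = 6,   na = 10,   fv = 100, al = 0),
                    u = c(pr = 7,  li = 7,   sf = .35, cb = 18, su = .08, ad = .20, fi = 3.5, na = 520,  fv = 55,  al = 0)),
  meat       = list(h = c(pr = 21, li = 12,  sf = .28, cb = 0.5, su = 0,  ad = 0,   fi = 0,   na = 70,   fv = 0,   al = 0),
                    u = c(pr = 15, li = 26,  sf = .55, cb = 1,  su = 0,   ad = 0,   fi = 0,   na = 950,  fv = 0,   al = 0)),
  fish       = list(h = c(pr = 19, li = 7,   sf = .20, cb = 0.5, su = 0,  ad = 0,   fi = 0,   na = 80,   fv = 0,   al = 0),
                    u = c(pr = 13, li = 16,  sf = .46, cb = 10, su = .05, ad = 0,   fi = 0.5, na = 1050, fv = 0,   al = 0)),
  processed  = list(h = c(pr = 19, li = 9,   sf = .32, cb = 1,  su = .30, ad = 0,   fi = 0,   na = 750,  fv = 0,   al = 0),
                    u = c(pr = 12, li = 30,  sf = .48, cb = 2,  su = .30, ad = 0,   fi = 0,   na = 1500, fv = 0,   al = 0)),
  egg        = list(h = c(pr = 12.5, li = 9.5, sf = .28, cb = 1,  su = .30, ad = 0,   fi = 0,   na = 130,  fv = 0,   al = 0),
                    u = c(pr = 10, li = 17,  sf = .40, cb = 3,  su = .30, ad = 0,   fi = 0,   na = 480,  fv = 0,   al = 0)),
  dairy_sweet = list(h = c(pr = 4, li = 4.5, sf = .50, cb = 14, su = .80, ad = .50, fi = 0.2, na = 60,   fv = 0,   al = 0),
                    u = c(pr = 3,  li = 9.5, sf = .72, cb = 26, su = .85, ad = .80, fi = 0.2, na = 95,   fv = 0,   al = 0)),
  cheese     = list(h = c(pr = 25, li = 19,  sf = .58, cb = 1,  su = .80, ad = 0,   fi = 0,   na = 350,  fv = 0,   al = 0),
                    u = c(pr = 17, li = 33,  sf = .72, cb = 1.5, su = .80, ad = 0,  fi = 0,   na = 1250, fv = 0,   al = 0)),
  milk       = list(h = c(pr = 3.3, li = 1,  sf = .65, cb = 5,  su = 1,   ad = 0,   fi = 0,   na = 45,   fv = 0,   al = 0),
                    u = c(pr = 3.2, li = 3.8, sf = .67, cb = 11, su = .92, ad = .45, fi = 0.1, na = 65,  fv = 0,   al = 0)),
  dairy_plain = list(h = c(pr = 4.5, li = 2.6, sf = .62, cb = 5,  su = .90, ad = 0,   fi = 0,   na = 50,   fv = 0,   al = 0),
                    u = c(pr = 3.5, li = 4,  sf = .65, cb = 16, su = .85, ad = .60, fi = 0.1, na = 65,   fv = 0,   al = 0)),
  fat        = list(h = c(pr = 0,  li = 92,  sf = .12, cb = 0.2, su = 0,  ad = 0,   fi = 0,   na = 5,    fv = 0,   al = 0),
                    u = c(pr = 0.7, li = 82, sf = .64, cb = 0.8, su = .50, ad = 0,  fi = 0,   na = 650,  fv = 0,   al = 0)),
  sweet_baked = list(h = c(pr = 7, li = 15,  sf = .25, cb = 46, su = .30, ad = .80, fi = 2.5, na = 180,  fv = 0,   al = 0),
                    u = c(pr = 5,  li = 25,  sf = .58, cb = 62, su = .60, ad = .95, fi = 1.2, na = 480,  fv = 0,   al = 0)),
  sweet      = list(h = c(pr = 3,  li = 12,  sf = .40, cb = 72, su = .85, ad = .95, fi = 0.5, na = 30,   fv = 0,   al = 0),
                    u = c(pr = 5,  li = 30,  sf = .62, cb = 58, su = .90, ad = .95, fi = 1.5, na = 110,  fv = 0,   al = 0)),
  snack      = list(h = c(pr = 7,  li = 21,  sf = .12, cb = 52, su = .04, ad = 0,   fi = 4,   na = 480,  fv = 0,   al = 0),
                    u = c(pr = 6,  li = 33,  sf = .40, cb = 50, su = .08, ad = .30, fi = 1.8, na = 1350, fv = 0,   al = 0)),
  dried_fruit = list(h = c(pr = 3, li = 1,   sf = .20, cb = 62, su = .90, ad = 0,   fi = 7,   na = 10,   fv = 0,   al = 0),
                    u = c(pr = 9,  li = 46,  sf = .25, cb = 22, su = .50, ad = .30, fi = 5.5, na = 320,  fv = 0,   al = 0)),
  sweet_drink = list(h = c(pr = 0, li = 0,   sf = 0,   cb = 2.5, su = 1,  ad = 1,   fi = 0,   na = 10,   fv = 0,   al = 0),
                    u = c(pr = 0,  li = 0,   sf = 0,   cb = 13, su = 1,   ad = 1,   fi = 0,   na = 25,   fv = 0,   al = 0)),
  juice      = list(h = c(pr = 0.5, li = 0.1, sf = .20, cb = 9, su = 1,   ad = 0,   fi = 0.4, na = 4,    fv = 90,  al = 0),
                    u = c(pr = 0.3, li = 0.1, sf = .20, cb = 13, su = 1,  ad = .40, fi = 0.1, na = 10,   fv = 40,  al = 0)),
  water      = list(h = c(pr = 0,  li = 0,   sf = 0,   cb = 0,  su = 0,   ad = 0,   fi = 0,   na = 1,    fv = 0,   al = 0),
                    u = c(pr = 0,  li = 0,   sf = 0,   cb = 0,  su = 0,   ad = 0,   fi = 0,   na = 5,    fv = 0,   al = 0)),
  hot_bev    = list(h = c(pr = 0.2, li = 0,  sf = 0,   cb = 0.3, su = .30, ad = 0,  fi = 0,   na = 2,    fv = 0,   al = 0),
                    u = c(pr = 0.3, li = 0.2, sf = .50, cb = 0.8, su = .40, ad = .40, fi = 0, na = 4,    fv = 0,   al = 0)),
  alcohol    = list(h = c(pr = 0.3, li = 0,  sf = 0,   cb = 2,  su = .40, ad = 0,   fi = 0,   na = 5,    fv = 0,   al = 3.5),
                    u = c(pr = 0.1, li = 0,  sf = 0,   cb = 6,  su = .60, ad = .30, fi = 0,   na = 10,   fv = 0,   al = 13))
)

# internal: compose nutrient fields from an archetype at intensity q with
# multiplicative noise
compose_food <- function(arch, q, noise_sd = 0.12) {
  h <- arch$h
  u <- arch$u
  v <- pmax(h + q * (u - h), 0)
  jitter <- stats::rlnorm(6, 0, noise_sd)
  pr <- v[["pr"]] * jitter[1]
  li <- v[["li"]] * jitter[2]
  cb <- v[["cb"]] * jitter[3]
  fi <- v[["fi"]] * jitter[4]
  na <- v[["na"]] * jitter[5]
  al <- v[["al"]] * jitter[6]
  sug <- cb * min(1, v[["su"]])
  kcal <- 4 * (cb + pr) + 9 * li + 7 * al
  tibble::tibble(
    energy_kcal = kcal,
    energy_kj = kcal * 4.184,
    protein_g = pr,
    carb_g = cb,
    sugars_g = sug,
    added_sugars_g = sug * min(1, v[["ad"]]),
    lipid_g = li,
    saturates_g = li * min(1, v[["sf"]]),
    fibre_g = fi,
    sodium_mg = na,
    fvln_percent = min(100, max(0, v[["fv"]] * stats::rlnorm(1, 0, 0.05))),
    alcohol_g = al
  )
}

#' Generate a synthetic scored food table
#'
#' Draws per-group compositions between a healthy and an unhealthy
#' archetype pole, steering each food towards a target colour class so
#' that all five classes are represented in most groups (bounded redraws;
#' a warning reports any colour with no food at all). Compositions are
#' internally consistent (energy from Atwater factors; sugars within
#' carbohydrates; saturates within lipids) and are scored before emission.
#'
#' @param n_foods Total number of foods (>= 5 per group).
#' @param groups Group taxonomy, as [default_food_groups()].
#' @param seed Integer seed.
#' @param config A [cnl_config()] list.
#' @return Scored food tibble (composition columns, flags, `fsa_score`,
#'   `colour`).
#' @export
generate_food_table <- function(n_foods = 200,
                                groups = default_food_groups(),
                                seed = 1L, config = cnl_config()) {
  if (n_foods < 5 * nrow(groups)) {
    stop("need at least 5 foods per group (", 5 * nrow(groups), ")")
  }
  set.seed(seed)
  per_group <- rep(n_foods %/% nrow(groups), nrow(groups))
  extra <- n_foods %% nrow(groups)
  if (extra > 0) per_group[seq_len(extra)] <- per_group[seq_len(extra)] + 1
  rows <- vector("list", n_foods)
  fid <- 0L
  for (gi in seq_len(nrow(groups))) {
    g <- groups[gi, ]
    arch <- .archetypes[[g$archetype]]
    flagged <- g$archetype %in% c("water", "hot_bev")
    targets <- rep(cnl_colours(), length.out = per_group[gi])
    for (tcol in targets) {
      fid <- fid + 1L
      if (flagged || g$archetype == "alcohol") {
        comp <- compose_food(arch, stats::runif(1), 0.1)
      } else {
        trank <- colour_rank(tcol)
        q <- (trank - 1) / 4 + stats::runif(1, -0.1, 0.1)
        comp <- NULL
        for (try in 1:25) {
          q <- min(1.3, max(-0.15, q))
          cand <- compose_food(arch, q)
          s <- fsa_score(c(as.list(cand), category = g$category), config)
          crank <- colour_rank(allocate_class(
            s$total, g$category, FALSE, FALSE, config))
          if (is.null(comp) || abs(crank - trank) < comp$dist) {
            comp <- list(row = cand, dist = abs(crank - trank))
          }
          if (crank == trank) break
          q <- q + 0.12 * (trank - crank)
        }
        comp <- comp$row
      }
      comp$food_id <- sprintf("F%04d", fid)
      comp$name <- paste0(g$group_id, "_", fid)
      comp$group_id <- g$group_id
      comp$category <- g$category
      comp$is_plain_water <- g$archetype == "water"
      comp$is_unsweetened_hot_beverage <- g$archetype == "hot_bev"
      comp$is_alcoholic <- g$archetype == "alcohol"
      rows[[fid]] <- comp
    }
  }
  foods <- score_foods(dplyr::bind_rows(rows), config)
  present <- unique(foods$colour[!foods$is_alcoholic])
  missing <- setdiff(cnl_colours(), present)
  if (length(missing)) {
    warning("no food achieved colour class(es): ",
            paste(missing, collapse = ", "))
  }
  foods
}

#' Default dietary-profile specifications
#'
#' Three latent profiles with target colour-share means and SDs matching
#' the three observed dietary patterns (Healthy / Western / Traditional),
#' mixture weights matching their population proportions, and qualitative
#' food-group propensities (affinity multipliers on food sampling).
#'
#' @return Named list of profile specs.
#' @export
default_profiles <- function() {
  norm100 <- function(x) 100 * x / sum(x)
  list(
    Healthy = list(
      weight = 0.293,
      mean = norm100(c(green = 44, yellow = 13.8, orange = 13.2,
                       pink = 20.6, red = 8.31)),
      sd = c(green = 9.81, yellow = 7.63, orange = 8.62, pink = 8.22,
             red = 6.84),
      alcohol_share = 0.030,
      affinity = c(fruits = 3, vegetables = 3, whole_grains = 3,
                   fish = 2.5, legumes = 2.5, yogurt = 2,
                   soft_drinks = 0.3, pastries = 0.3,
                   processed_meat = 0.4, confectionery = 0.5)
    ),
    Western = list(
      weight = 0.348,
      mean = norm100(c(green = 21.2, yellow = 14.6, orange = 11.7,
                       pink = 40.3, red = 12.2)),
      sd = c(green = 7.93, yellow = 6.88, orange = 7.51, pink = 7.94,
             red = 7.88),
      alcohol_share = 0.045,
      affinity = c(soft_drinks = 3, juices = 2, breakfast_cereals = 2.5,
                   cheese = 2.5, pastries = 3, biscuits_cakes = 3,
                   confectionery = 2, salty_snacks = 2,
                   fruits = 0.5, vegetables = 0.5, whole_grains = 0.4)
    ),
    Traditional = list(
      weight = 0.351,
      mean = norm100(c(green = 22.5, yellow = 27.3, orange = 13.1,
                       pink = 22.8, red = 14.4)),
      sd = c(green = 7.29, yellow = 9.05, orange = 8.39, pink = 6.94,
             red = 9.16),
      alcohol_share = 0.050,
      affinity = c(bread_pasta_rice = 3, potatoes = 2.5, meat = 2.5,
                   dairy_desserts = 2.5, processed_meat = 2, fats = 1.8,
                   whole_grains = 0.5, breakfast_cereals = 0.5)
    )
  )
}

# internal: draw n colour-share vectors Gaussian around `m` with SDs `sd`
# on the 100-simplex. Negative draws are clamped at zero and rows
# renormalised; a short self-calibration pass pre-shifts the latent means
# so the realised means match the targets despite clamping.
draw_colour_shares <- function(n, m, sd, calibrate_n = 20000) {
  raw <- function(mu, z) {
    s <- sweep(sweep(z, 2, sd, "*"), 2, mu, "+")
    s[s < 0] <- 0
    zero <- rowSums(s) <= 0
    if (any(zero)) s[zero, ] <- matrix(mu, sum(zero), length(mu),
                                       byrow = TRUE)
    100 * s / rowSums(s)
  }
  zc <- matrix(stats::rnorm(calibrate_n * length(m)), ncol = length(m))
  mu <- m
  for (it in 1:6) mu <- mu + (m - colMeans(raw(mu, zc)))
  raw(mu, matrix(stats::rnorm(n * length(m)), ncol = length(m)))
}

#' Generate a synthetic population with 24-h records and ground truth
#'
#' Each person is assigned a latent dietary profile (mixture weights from
#' the profile specs), anthropometrics from plausible adult ranges, and
#' three 24-h records (two weekday, one weekend). Food events are sampled
#' per colour class — with the profile's food-group propensities — and
#' quantities are set so each record's colour energy split equals the
#' person's target shares, themselves Gaussian around the profile means.
#' Reported intake is centred on expenditure (Schofield BMR times PAL);
#' a configurable fraction of deliberate under-reporters has all
#' quantities scaled so reported energy equals `under_report_factor`
#' times expenditure.
#'
#' @param n Number of persons.
#' @param foods A scored food table ([generate_food_table()]).
#' @param profiles Profile specs ([default_profiles()]).
#' @param seed Integer seed for all draws.
#' @param config A [cnl_config()] list.
#' @param under_reporter_frac Fraction of deliberate under-reporters.
#' @param under_report_factor Reported/expenditure energy ratio of
#'   under-reporters.
#' @return List: `persons`, `records`, `truth` (per-person latent profile,
#'   target shares, under-reporter flag).
#' @export
generate_population <- function(n, foods, profiles = default_profiles(),
                                seed = 1L, config = cnl_config(),
                                under_reporter_frac = 0.10,
                                under_report_factor = 0.60) {
  empty <- list(
    persons = tibble::tibble(person_id = character(), sex = character(),
                             age_years = numeric(), weight_kg = numeric(),
                             height_m = numeric(), pal = character()),
    records = tibble::tibble(person_id = character(),
                             record_index = integer(),
                             day_type = character(), food_id = character(),
                             quantity_g = numeric()),
    truth = tibble::tibble(person_id = character(), profile = character(),
                           under_reporter = logical())
  )
  if (n == 0) return(empty)
  set.seed(seed)
  weights <- vapply(profiles, `[[`, numeric(1), "weight")
  weights <- weights / sum(weights)

  pool <- foods[!foods$is_alcoholic & foods$energy_kcal >= 15, , drop = FALSE]
  colour_pools <- split(seq_len(nrow(pool)), pool$colour)
  missing <- setdiff(cnl_colours(), names(colour_pools))
  if (length(missing)) {
    warning("food table lacks colour(s) ", paste(missing, collapse = ", "),
            "; their target energy is diverted to the nearest class")
  }
  water_rows <- which(foods$is_plain_water)
  alcohol_rows <- which(foods$is_alcoholic)

  sex <- sample(c("female", "male"), n, replace = TRUE,
                prob = c(0.781, 0.219))
  age <- pmin(pmax(stats::rnorm(n, 43.1, 14.6), 18.5), 85)
  height <- ifelse(sex == "female", stats::rnorm(n, 1.63, 0.06),
                   stats::rnorm(n, 1.76, 0.07))
  bmi <- pmin(pmax(stats::rnorm(n, 23.5, 3.5), 16.5), 40)
  weight <- bmi * height^2
  pal <- sample(names(config$pal_map), n, replace = TRUE,
                prob = c(0.3, 0.5, 0.2))
  persons <- tibble::tibble(
    person_id = sprintf("P%05d", seq_len(n)),
    sex = sex, age_years = age, weight_kg = weight, height_m = height,
    pal = pal)

  profile_of <- sample(names(profiles), n, replace = TRUE, prob = weights)
  shares_by_profile <- lapply(names(profiles), function(pn) {
    idx <- which(profile_of == pn)
    if (!length(idx)) return(NULL)
    draw_colour_shares(length(idx), profiles[[pn]]$mean,
                       profiles[[pn]]$sd)
  })
  names(shares_by_profile) <- names(profiles)
  target_shares <- matrix(NA_real_, n, 5,
                          dimnames = list(NULL, tolower(cnl_colours())))
  for (pn in names(profiles)) {
    idx <- which(profile_of == pn)
    if (length(idx)) target_shares[idx, ] <- shares_by_profile[[pn]]
  }

  bmr <- schofield_bmr(sex, age, weight, config)
  expenditure <- bmr * unname(config$pal_map[pal])
  ei_target <- expenditure * stats::rlnorm(n, 0, 0.09)
  under <- stats::runif(n) < under_reporter_frac
  drinker <- stats::runif(n) < 0.6

  day_types <- c("weekday", "weekday", "weekend")
  day_base <- c(0.96, 0.96, 1.10)  # weekend records run a little richer

  grp <- default_food_groups()
  base_w <- stats::setNames(grp$base_weight, grp$group_id)
  pool_base <- base_w[pool$group_id]
  pool_base[is.na(pool_base)] <- 1

  rec_list <- vector("list", n)
  for (i in seq_len(n)) {
    prof <- profiles[[profile_of[i]]]
    aff <- as.numeric(pool_base)
    if (length(prof$affinity)) {
      hit <- match(pool$group_id, names(prof$affinity))
      aff[!is.na(hit)] <- aff[!is.na(hit)] * prof$affinity[hit[!is.na(hit)]]
    }
    alc_frac <- if (drinker[i]) {
      min(0.15, prof$alcohol_share * stats::rlnorm(1, 0, 0.5))
    } else {
      0
    }
    fid <- character(0)
    qty <- numeric(0)
    rec <- integer(0)
    for (r in 1:3) {
      e_day <- ei_target[i] * day_base[r] * stats::rlnorm(1, 0, 0.05)
      e_nonalc <- e_day * (1 - alc_frac)
      for (ci in seq_along(cnl_colours())) {
        cl <- cnl_colours()[ci]
        e_c <- e_nonalc * target_shares[i, ci] / 100
        if (e_c <= 1) next
        rows_c <- colour_pools[[cl]]
        if (is.null(rows_c)) {
          nxt <- intersect(cnl_colours()[order(abs(seq_len(5) - ci))],
                           names(colour_pools))[1]
          rows_c <- colour_pools[[nxt]]
        }
        n_ev <- max(1L, min(5L, round(e_c / 250)))
        picked <- sample(rows_c, n_ev, replace = TRUE,
                         prob = aff[rows_c])
        alloc <- stats::rgamma(n_ev, 1.5)
        alloc <- e_c * alloc / sum(alloc)
        fid <- c(fid, pool$food_id[picked])
        qty <- c(qty, 100 * alloc / pool$energy_kcal[picked])
        rec <- c(rec, rep(r, n_ev))
      }
      if (alc_frac > 0 && length(alcohol_rows)) {
        a <- sample(alcohol_rows, 1)
        fid <- c(fid, foods$food_id[a])
        qty <- c(qty, 100 * e_day * alc_frac / foods$energy_kcal[a])
        rec <- c(rec, r)
      }
      if (length(water_rows)) {
        w <- sample(water_rows, 1)
        fid <- c(fid, foods$food_id[w])
        qty <- c(qty, stats::runif(1, 150, 600))
        rec <- c(rec, r)
      }
    }
    rec_list[[i]] <- tibble::tibble(
      person_id = persons$person_id[i],
      record_index = rec,
      day_type = day_types[rec],
      food_id = fid,
      quantity_g = qty)
  }
  records <- dplyr::bind_rows(rec_list)

  # scale under-reporters so reported energy is exactly the configured
  # fraction of expenditure
  if (any(under)) {
    meta <- dplyr::distinct(records, .data$person_id, .data$record_index,
                            .data$day_type)
    w <- record_weights(meta, config)
    ev <- dplyr::inner_join(records, w,
                            by = c("person_id", "record_index", "day_type"))
    ev <- dplyr::inner_join(ev, foods[, c("food_id", "energy_kcal")],
                            by = "food_id")
    realized <- dplyr::summarise(
      dplyr::group_by(ev, .data$person_id),
      ei = sum(.data$quantity_g * .data$weight / 100 * .data$energy_kcal),
      .groups = "drop")
    scale_tab <- tibble::tibble(
      person_id = persons$person_id,
      scale = ifelse(under, under_report_factor * expenditure /
                       realized$ei[match(persons$person_id,
                                         realized$person_id)], 1))
    records <- dplyr::inner_join(records, scale_tab, by = "person_id")
    records$quantity_g <- records$quantity_g * records$scale
    records$scale <- NULL
  }

  truth <- tibble::tibble(
    person_id = persons$person_id,
    profile = profile_of,
    under_reporter = under,
    expenditure = expenditure,
    target_ei = ifelse(under, under_report_factor * expenditure, ei_target))
  truth <- dplyr::bind_cols(truth, tibble::as_tibble(target_shares))
  list(persons = persons, records = records, truth = truth)
}
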