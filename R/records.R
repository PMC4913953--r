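#' @importFrom rlang .data
NULL

# nutrient columns carried through intake computation (per 100 g in the
# food table; per day after weighting)
.nutrient_cols <- c("energy_kcal", "carb_g", "sugars_g", "added_sugars_g",
                    "lipid_g", "saturates_g", "protein_g", "fibre_g",
                    "sodium_mg", "alcohol_g")

# internal: per-record day weights for one set of record metadata.
# Generic rule: weight(record) = (days of its type per week / 7) divided by
# the number of records of that type. When a day type has no record at all
# the remaining weights are renormalised to 1 (the observed days stand in
# for the whole week).
record_weights <- function(meta, config = cnl_config()) {
  stopifnot(all(c("person_id", "record_index", "day_type") %in% names(meta)))
  shares <- config$day_weights
  bad <- setdiff(unique(meta$day_type), names(shares))
  if (length(bad)) stop("unknown day type(s): ", paste(bad, collapse = ", "))
  counts <- dplyr::count(meta, .data$person_id, .data$day_type)
  counts$type_share <- unname(shares[counts$day_type])
  counts <- dplyr::mutate(dplyr::group_by(counts, .data$person_id),
                          present_share = sum(.data$type_share))
  counts <- dplyr::ungroup(counts)
  counts$weight <- counts$type_share / counts$n / counts$present_share
  dplyr::inner_join(meta, counts[, c("person_id", "day_type", "weight")],
                    by = c("person_id", "day_type"))
}

#' Weighted daily intakes for a population of 24-h records
#'
#' Assembles each person's mean daily intake from repeated 24-h records,
#' weighting each record by the representativeness of its day of the week
#' (default five weekdays and two weekend days, so two weekday records get
#' 5/14 each and the weekend record 2/7). Nutrients are computed from the
#' per-100 g food composition table; energy is also split by the food's
#' 5-CNL colour, with alcoholic-beverage energy kept apart.
#'
#' @param records Data frame with columns `person_id`, `record_index`,
#'   `day_type` (`"weekday"`/`"weekend"`), `food_id`, `quantity_g`.
#' @param foods A scored food table ([score_foods()]) whose rows cover all
#'   `food_id`s, carrying the nutrient columns per 100 g and `colour`,
#'   `is_alcoholic`.
#' @param config A [cnl_config()] list.
#' @param record_meta Optional data frame `person_id`, `record_index`,
#'   `day_type` declaring all records (including any with no events, whose
#'   day weight then still counts); defaults to the records present in
#'   `records`.
#' @return A list of class `individual_diets`: `nutrients` (one row per
#'   person: daily nutrients, `energy_colour_*` kcal/d over non-alcoholic
#'   foods, `energy_alcohol`), and `food_quantities` (person x food mean
#'   daily grams).
#' @export
compute_daily_intakes <- function(records, foods, config = cnl_config(),
                                  record_meta = NULL) {
  stopifnot(is.data.frame(records), is.data.frame(foods))
  need <- c("person_id", "record_index", "day_type", "food_id", "quantity_g")
  missing <- setdiff(need, names(records))
  if (length(missing)) stop("records missing column(s): ",
                            paste(missing, collapse = ", "))
  if (any(!is.finite(records$quantity_g)) || any(records$quantity_g < 0)) {
    stop("quantities must be finite and non-negative")
  }
  unknown <- setdiff(unique(records$food_id), foods$food_id)
  if (length(unknown)) {
    stop("unknown food id(s) in records: ",
         paste(utils::head(unknown, 10), collapse = ", "))
  }
  if (is.null(foods$colour)) {
    stop("food table is not scored; run score_foods() first")
  }

  meta <- record_meta %||% dplyr::distinct(records, .data$person_id,
                                           .data$record_index, .data$day_type)
  meta <- record_weights(meta, config)
  ev <- dplyr::inner_join(records, meta,
                          by = c("person_id", "record_index", "day_type"))
  ev <- dplyr::inner_join(
    ev, foods[, c("food_id", .nutrient_cols, "colour", "is_alcoholic")],
    by = "food_id")
  ev$wq <- ev$quantity_g * ev$weight  # weighted grams/day

  quantities <- dplyr::summarise(
    dplyr::group_by(ev, .data$person_id, .data$food_id),
    qty_g_day = sum(.data$wq), .groups = "drop")

  per_nutrient <- lapply(.nutrient_cols, function(nc) {
    stats::setNames(
      dplyr::summarise(dplyr::group_by(ev, .data$person_id),
                       x = sum(.data$wq / 100 * .data[[nc]]),
                       .groups = "drop"),
      c("person_id", nc))
  })
  nutrients <- Reduce(function(a, b) dplyr::full_join(a, b, by = "person_id"),
                      per_nutrient)

  ev$colour_nonalc <- ifelse(ev$is_alcoholic, "ALCOHOL", ev$colour)
  by_col <- dplyr::summarise(
    dplyr::group_by(ev, .data$person_id, .data$colour_nonalc),
    e = sum(.data$wq / 100 * .data$energy_kcal), .groups = "drop")
  by_col <- tidyr::pivot_wider(by_col, names_from = "colour_nonalc",
                               values_from = "e", values_fill = 0)
  for (cl in c(cnl_colours(), "ALCOHOL")) {
    if (is.null(by_col[[cl]])) by_col[[cl]] <- 0
  }
  colour_cols <- stats::setNames(
    by_col[, c("person_id", cnl_colours(), "ALCOHOL")],
    c("person_id", paste0("energy_colour_", tolower(cnl_colours())),
      "energy_alcohol"))

  nutrients <- dplyr::left_join(nutrients, colour_cols, by = "person_id")
  structure(list(nutrients = tibble::as_tibble(nutrients),
                 food_quantities = quantities),
            class = "individual_diets")
}

#' Weighted daily intake of a single person
#'
#' Convenience wrapper around [compute_daily_intakes()] for one person's
#' records; enforces the configured record mix (default two weekday plus
#' one weekend record) unless `strict = FALSE`, in which case any mix is
#' re-weighted by the generic day-share rule.
#'
#' @inheritParams compute_daily_intakes
#' @param strict Require exactly the configured day-type mix.
#' @return One-row `individual_diets` object.
#' @export
weighted_daily_intake <- function(records, foods, config = cnl_config(),
                                  strict = TRUE, record_meta = NULL) {
  stopifnot(length(unique(records$person_id)) == 1L)
  meta <- record_meta %||%
    dplyr::distinct(records, .data$person_id, .data$record_index,
                    .data$day_type)
  counts <- table(factor(meta$day_type, names(config$expected_records)))
  if (strict && !all(counts == config$expected_records)) {
    stop("expected record mix ",
         paste(sprintf("%d %s", config$expected_records,
                       names(config$expected_records)), collapse = " + "),
         "; got ", paste(sprintf("%d %s", counts, names(counts)),
                         collapse = " + "))
  }
  compute_daily_intakes(records, foods, config, record_meta = record_meta)
}

#' Schofield basal metabolic rate
#'
#' Age- and sex-banded linear prediction of BMR (kcal/day) from body
#' weight, using the coefficient table in the configuration. Adults only.
#'
#' @param sex `"male"` or `"female"`.
#' @param age_years Age in years (> 18).
#' @param weight_kg Body weight, kg.
#' @param config A [cnl_config()] list.
#' @return BMR in kcal/day.
#' @export
#' @examples
#' schofield_bmr("male", 30, 70)
schofield_bmr <- function(sex, age_years, weight_kg, config = cnl_config()) {
  stopifnot(length(sex) == length(age_years),
            length(sex) == length(weight_kg))
  if (any(age_years < 18)) {
    stop("Schofield bands for this pipeline cover adults only (age >= 18)")
  }
  if (any(weight_kg <= 0)) stop("weight must be positive")
  tab <- config$schofield
  vapply(seq_along(sex), function(i) {
    band <- tab[tab$sex == sex[i] & age_years[i] >= tab$age_min &
                  age_years[i] < tab$age_max, ]
    if (nrow(band) != 1L) stop("no Schofield band for sex=", sex[i],
                               " age=", age_years[i])
    band$a * weight_kg[i] + band$b
  }, numeric(1))
}

#' Goldberg lower confidence-limit cut-off on EI/BMR
#'
#' Computes the lower confidence limit of the energy-intake to BMR ratio
#' under which reported intake is implausibly low (Goldberg/Black):
#' `PAL * exp(-z * S / 100 / sqrt(n))` with
#' `S = sqrt(CVwEI^2 / d + CVwB^2 + CVtP^2)`,
#' where `d` is the number of record days and `n` the number of subjects
#' evaluated jointly (1 for individual screening).
#'
#' @param pal Physical activity level multiplier used as the plausibility
#'   reference (the individual's own, or a population value).
#' @param config A [cnl_config()] list (element `goldberg`).
#' @return The EI/BMR cut-off.
#' @export
goldberg_cutoff <- function(pal, config = cnl_config()) {
  g <- config$goldberg
  z <- stats::qnorm(1 - (1 - g$confidence) / 2)
  s <- sqrt(g$cv_within_ei^2 / g$days + g$cv_bmr^2 + g$cv_pal^2)
  pal * exp(-z * (s / 100) / sqrt(g$n))
}

#' Flag energy under-reporters
#'
#' TRUE when reported energy intake divided by BMR falls below the
#' Goldberg cut-off.
#'
#' @param energy_intake Reported mean daily energy intake, kcal/d.
#' @param bmr Basal metabolic rate, kcal/d (positive).
#' @param pal PAL multiplier (recycled); with
#'   `config$goldberg$pal_source == "population"` the configured
#'   population PAL is used instead.
#' @param config A [cnl_config()] list.
#' @return Logical vector.
#' @export
goldberg_underreporter <- function(energy_intake, bmr, pal = NULL,
                                   config = cnl_config()) {
  if (any(bmr <= 0)) stop("bmr must be positive")
  if (any(energy_intake < 0)) stop("energy intake must be non-negative")
  g <- config$goldberg
  pal_ref <- if (identical(g$pal_source, "population") || is.null(pal)) {
    g$population_pal
  } else {
    pal
  }
  energy_intake / bmr < goldberg_cutoff(pal_ref, config)
}

#' Screen a population for energy under-reporting
#'
#' Joins person attributes to computed intakes, evaluates the Schofield
#' BMR, expenditure (BMR x PAL multiplier) and the Goldberg flag per
#' person.
#'
#' @param diets An `individual_diets` object.
#' @param persons Data frame with `person_id`, `sex`, `age_years`,
#'   `weight_kg`, `height_m`, `pal` (levels of `config$pal_map`).
#' @param config A [cnl_config()] list.
#' @return `persons` with added `bmr`, `pal_multiplier`, `expenditure`,
#'   `energy_intake`, `under_reporter`.
#' @export
screen_underreporters <- function(diets, persons, config = cnl_config()) {
  stopifnot(inherits(diets, "individual_diets"))
  bad_pal <- setdiff(unique(persons$pal), names(config$pal_map))
  if (length(bad_pal)) stop("unknown PAL level(s): ",
                            paste(bad_pal, collapse = ", "))
  out <- dplyr::inner_join(
    persons, diets$nutrients[, c("person_id", "energy_kcal")],
    by = "person_id")
  out$bmr <- schofield_bmr(out$sex, out$age_years, out$weight_kg, config)
  out$pal_multiplier <- unname(config$pal_map[out$pal])
  out$expenditure <- out$bmr * out$pal_multiplier
  out$energy_intake <- out$energy_kcal
  out$energy_kcal <- NULL
  out$under_reporter <- goldberg_underreporter(
    out$energy_intake, out$bmr, out$pal_multiplier, config)
  tibble::as_tibble(out)
}

#' Colour energy shares of individual diets
#'
#' Percentage of daily non-alcohol energy supplied by foods of each 5-CNL
#' colour; energy from alcoholic beverages is excluded from numerator and
#' denominator. The five shares sum to 100.
#'
#' @param diets An `individual_diets` object, or its `nutrients` table.
#' @return Tibble with `person_id` and columns `green`, `yellow`,
#'   `orange`, `pink`, `red`.
#' @export
colour_energy_shares <- function(diets) {
  nutr <- if (inherits(diets, "individual_diets")) diets$nutrients else diets
  cols <- paste0("energy_colour_", tolower(cnl_colours()))
  stopifnot(all(cols %in% names(nutr)))
  total <- rowSums(nutr[, cols])
  if (any(total <= 0)) {
    stop("zero non-alcohol energy for person(s): ",
         paste(utils::head(nutr$person_id[total <= 0], 10), collapse = ", "))
  }
  out <- tibble::tibble(person_id = nutr$person_id)
  for (i in seq_along(cols)) {
    out[[tolower(cnl_colours())[i]]] <- 100 * nutr[[cols[i]]] / total
  }
  out
}
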