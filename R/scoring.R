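#' Points for one score component
#'
#' Looks up the points awarded to a nutrient value in a threshold/point
#' step table: the points of the highest threshold *strictly* exceeded,
#' or 0 when no threshold is exceeded. Non-decreasing in the value and
#' saturating at the table's maximum.
#'
#' @param value Non-negative finite nutrient value (per 100 g).
#' @param table A point table: list with `thresholds` and `points`.
#' @return Integer points.
#' @export
#' @examples
#' component_points(10000, default_point_tables()$energy)  # saturates at 10
component_points <- function(value, table) {
  if (length(value) != 1L || !is.finite(value)) {
    stop("component value must be a single finite number")
  }
  if (value < 0) stop("component value must be non-negative, got ", value)
  exceeded <- which(value > table$thresholds)
  if (!length(exceeded)) return(0L)
  table$points[max(exceeded)]
}

# internal: required nutrient fields for scoring
.score_fields <- c("energy_kj", "sugars_g", "saturates_g", "sodium_mg",
                   "fvln_percent", "fibre_g", "protein_g", "lipid_g")

.food_categories <- c("general_food", "beverage", "cheese", "added_fat",
                      "dried_fruit_nut")

# internal: validate a single food composition (list-like)
validate_composition <- function(food) {
  missing <- setdiff(.score_fields, names(food))
  missing <- c(missing, .score_fields[vapply(
    intersect(.score_fields, names(food)),
    function(f) is.null(food[[f]]) || is.na(food[[f]]), logical(1))])
  if (length(missing)) {
    stop("food composition is missing field(s): ",
         paste(unique(missing), collapse = ", "))
  }
  vals <- unlist(food[.score_fields])
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("nutrient fields must be finite and non-negative")
  }
  if (food$fvln_percent > 100) stop("fvln_percent must be <= 100")
  category <- food$category %||% "general_food"
  if (!category %in% .food_categories) {
    stop("unknown food category: ", category)
  }
  invisible(food)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Modified FSA nutrient-profile score of one food or beverage
#'
#' Computes the per-100 g score: unfavourable A-points (energy, total
#' sugars, saturates, sodium; 0-10 each) minus favourable C-points
#' (fruit/vegetables/legumes/nuts %, NSP fibre, protein; 0-5 each), with
#' the protein gate and the French category adaptations:
#'
#' * protein points are withheld when A-points reach the configured gate
#'   (default 11) and fvln points are below 5 — except for cheese, whose
#'   protein always counts;
#' * beverages are scored on dedicated energy and sugars tables;
#' * added fats replace the saturates component by the saturates-to-total-
#'   lipids ratio (%), scored on its own table.
#'
#' The total lives on a discrete scale from -15 (most favourable) to +40.
#'
#' @param food A list or one-row data frame with fields `energy_kj`,
#'   `sugars_g`, `saturates_g`, `sodium_mg`, `fvln_percent`, `fibre_g`,
#'   `protein_g`, `lipid_g`, and optionally `category` (default
#'   `general_food`).
#' @param config A [cnl_config()] list.
#' @return A list of class `fsa_score` with per-component points,
#'   `a_points`, `c_points` (all favourable points), `c_points_applied`,
#'   `protein_counted` and `total`.
#' @export
fsa_score <- function(food, config = cnl_config()) {
  if (is.data.frame(food)) food <- as.list(food[1, ])
  validate_composition(food)
  pt <- config$point_tables
  category <- food$category %||% "general_food"

  energy_tab <- if (category == "beverage") pt$energy_beverage else pt$energy
  sugars_tab <- if (category == "beverage") pt$sugars_beverage else pt$sugars

  p_energy <- component_points(food$energy_kj, energy_tab)
  p_sugars <- component_points(food$sugars_g, sugars_tab)
  if (category == "added_fat") {
    ratio <- if (food$lipid_g > 0) 100 * food$saturates_g / food$lipid_g else 0
    p_sat <- component_points(ratio, pt$sat_lipid_ratio)
  } else {
    p_sat <- component_points(food$saturates_g, pt$saturates)
  }
  p_sodium <- component_points(food$sodium_mg, pt$sodium)

  p_fvln <- component_points(food$fvln_percent, pt$fvln)
  p_fibre <- component_points(food$fibre_g, pt$fibre)
  p_protein <- component_points(food$protein_g, pt$protein)

  a_points <- p_energy + p_sugars + p_sat + p_sodium
  gate <- config$protein_gate
  protein_counted <-
    a_points < gate$a_threshold ||
    p_fvln >= gate$fvln_exempt_points ||
    (gate$cheese_exempt && category == "cheese")
  c_applied <- p_fvln + p_fibre + if (protein_counted) p_protein else 0L

  structure(list(
    components = c(energy = p_energy, sugars = p_sugars, saturates = p_sat,
                   sodium = p_sodium, fvln = p_fvln, fibre = p_fibre,
                   protein = p_protein),
    a_points = a_points,
    c_points = p_fvln + p_fibre + p_protein,
    c_points_applied = c_applied,
    protein_counted = protein_counted,
    total = a_points - c_applied
  ), class = "fsa_score")
}

#' @export
print.fsa_score <- function(x, ...) {
  cat("FSA score:", x$total,
      sprintf("(A = %d, C applied = %d%s)\n", x$a_points, x$c_points_applied,
              if (x$protein_counted) "" else ", protein withheld"))
  print(x$components)
  invisible(x)
}

#' Allocate the 5-CNL colour class of a scored food
#'
#' Foods use the printed cut-offs (Green -15..-1, Yellow 0..2, Orange
#' 3..10, Pink 11..18, Red >= 19). Beverages use the beverage scale
#' (Yellow up to 1, Orange 2..5, Pink 6..9, Red >= 10), with Green
#' reserved for plain water and unsweetened hot beverages regardless of
#' score.
#'
#' @param score Integer score in -15..40.
#' @param category Food category; `"beverage"` selects the beverage scale.
#' @param is_plain_water,is_unsweetened_hot_beverage Flags forcing Green
#'   for qualifying beverages.
#' @param config A [cnl_config()] list.
#' @return One of `"GREEN"`, `"YELLOW"`, `"ORANGE"`, `"PINK"`, `"RED"`.
#' @export
allocate_class <- function(score, category = "general_food",
                           is_plain_water = FALSE,
                           is_unsweetened_hot_beverage = FALSE,
                           config = cnl_config()) {
  if (length(score) != 1L || !is.finite(score)) stop("score must be finite")
  if (score < -15 || score > 40) {
    stop("score out of range [-15, 40]: ", score)
  }
  if (category == "beverage") {
    if (isTRUE(is_plain_water) || isTRUE(is_unsweetened_hot_beverage)) {
      return("GREEN")
    }
    cuts <- config$class_cutoffs$beverage
  } else {
    cuts <- config$class_cutoffs$food
  }
  for (cls in names(cuts)) if (score <= cuts[[cls]]) return(cls)
  "RED"
}

#' Score a food table and allocate colour classes
#'
#' Vectorises [fsa_score()] and [allocate_class()] over the rows of a food
#' composition table.
#'
#' @param foods Data frame with one row per food and the composition
#'   fields of [fsa_score()]; optional flag columns `is_plain_water`,
#'   `is_unsweetened_hot_beverage`, `is_alcoholic`.
#' @param config A [cnl_config()] list.
#' @return `foods` with added columns `a_points`, `c_points_applied`,
#'   `protein_counted`, `fsa_score` and `colour`.
#' @export
score_foods <- function(foods, config = cnl_config()) {
  stopifnot(is.data.frame(foods), nrow(foods) > 0)
  if (is.null(foods$category)) foods$category <- "general_food"
  for (flag in c("is_plain_water", "is_unsweetened_hot_beverage",
                 "is_alcoholic")) {
    if (is.null(foods[[flag]])) foods[[flag]] <- FALSE
  }
  res <- lapply(seq_len(nrow(foods)), function(i) {
    s <- fsa_score(as.list(foods[i, ]), config)
    cls <- allocate_class(s$total, foods$category[i],
                          foods$is_plain_water[i],
                          foods$is_unsweetened_hot_beverage[i], config)
    list(a = s$a_points, c = s$c_points_applied, pc = s$protein_counted,
         total = s$total, colour = cls)
  })
  foods$a_points <- vapply(res, `[[`, numeric(1), "a")
  foods$c_points_applied <- vapply(res, `[[`, numeric(1), "c")
  foods$protein_counted <- vapply(res, `[[`, logical(1), "pc")
  foods$fsa_score <- vapply(res, `[[`, numeric(1), "total")
  foods$colour <- vapply(res, `[[`, character(1), "colour")
  tibble::as_tibble(foods)
}

#' Brute-force enumeration of the achievable score range
#'
#' Enumerates every combination of per-component points achievable under
#' the configured tables — each A-component over its attainable point
#' values, each C-component likewise — applies the protein-gate rule, and
#' returns the minimum and maximum total score. With the default tables
#' this confirms the scale runs from -15 to +40.
#'
#' @param config A [cnl_config()] list.
#' @param category Category whose gate behaviour to enumerate (the cheese
#'   exemption changes which C combinations apply).
#' @return List with `min`, `max` and `n_combinations`.
#' @export
enumerate_score_range <- function(config = cnl_config(),
                                  category = "general_food") {
  pt <- config$point_tables
  attainable <- function(tab) unique(c(0L, tab$points))
  a_sets <- list(attainable(pt$energy), attainable(pt$sugars),
                 attainable(pt$saturates), attainable(pt$sodium))
  a_grid <- expand.grid(a_sets)
  a_tot <- rowSums(a_grid)
  c_grid <- expand.grid(fvln = attainable(pt$fvln),
                        fibre = attainable(pt$fibre),
                        protein = attainable(pt$protein))
  gate <- config$protein_gate
  cheese <- gate$cheese_exempt && category == "cheese"
  totals <- vapply(seq_len(nrow(c_grid)), function(j) {
    gated <- !cheese & a_tot >= gate$a_threshold &
      c_grid$fvln[j] < gate$fvln_exempt_points
    applied <- c_grid$fvln[j] + c_grid$fibre[j] +
      ifelse(gated, 0L, c_grid$protein[j])
    range(a_tot - applied)
  }, numeric(2))
  list(min = as.integer(min(totals[1, ])),
       max = as.integer(max(totals[2, ])),
       n_combinations = nrow(a_grid) * nrow(c_grid))
}
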