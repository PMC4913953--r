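#' Default FSA component point tables
#'
#' Threshold/point step functions for every component of the nutrient
#' profiling score, per 100 g of food or beverage. A-components (energy,
#' total sugars, saturates, sodium) score 0-10 unfavourable points;
#' C-components (fruit/vegetables/legumes/nuts percentage, NSP fibre,
#' protein) score 0-5 favourable points. Points are awarded for the highest
#' threshold *strictly* exceeded, the UK FSA/Ofcom convention.
#'
#' Three category-specific tables implement the French adaptations of the
#' model: beverages use dedicated (much steeper) energy and sugars tables,
#' and added fats replace the saturates component by the ratio of saturates
#' to total lipids (in %) scored on its own 0-10 table. The beverage and
#' added-fat thresholds are editable defaults transcribed from the French
#' agency reports that defined the 5-CNL class system; treat them as
#' assumptions and override via `cnl_config()` if you hold the source
#' tables.
#'
#' @return Named list of point tables, each a list with elements
#'   `thresholds` (strictly increasing numeric) and `points` (non-decreasing
#'   integer, same length).
#' @export
default_point_tables <- function() {
  pt <- function(thresholds, points) {
    stopifnot(length(thresholds) == length(points),
              !is.unsorted(thresholds, strictly = TRUE),
              !is.unsorted(points))
    list(thresholds = as.numeric(thresholds), points = as.integer(points))
  }
  list(
    # A-components, general foods
    energy    = pt(335 * 1:10, 1:10),          # kJ /100 g
    sugars    = pt(c(4.5, 9, 13.5, 18, 22.5, 27, 31, 36, 40, 45), 1:10),
    saturates = pt(1:10, 1:10),                # g /100 g
    sodium    = pt(90 * 1:10, 1:10),           # mg /100 g
    # C-components
    fvln      = pt(c(40, 60, 80), c(1L, 2L, 5L)),  # % fruit/veg/legumes/nuts
    fibre     = pt(c(0.7, 1.4, 2.1, 2.8, 3.5), 1:5),  # NSP g /100 g
    protein   = pt(c(1.6, 3.2, 4.8, 6.4, 8.0), 1:5),  # g /100 g
    # Beverage-specific A-tables (French adaptation)
    energy_beverage = pt(30 * 1:10, 1:10),     # kJ /100 g
    sugars_beverage = pt(1.5 * 1:10, 1:10),    # g /100 g
    # Added fats: saturates/total-lipids ratio (%) replaces saturates
    sat_lipid_ratio = pt(c(10, 16, 22, 28, 34, 40, 46, 52, 58, 64), 1:10)
  )
}

#' Default 5-CNL colour-class cut-offs
#'
#' Foods: Green -15..-1, Yellow 0..2, Orange 3..10, Pink 11..18, Red >= 19.
#' Beverages: Green is reserved for plain water and unsweetened hot
#' beverages; Yellow up to 1, Orange 2..5, Pink 6..9, Red >= 10.
#'
#' Each element gives the *upper* score bound of the first four classes;
#' anything above the last bound is Red.
#'
#' @return List with elements `food` and `beverage`.
#' @export
default_class_cutoffs <- function() {
  list(
    food     = c(GREEN = -1, YELLOW = 2, ORANGE = 10, PINK = 18),
    beverage = c(GREEN = -Inf, YELLOW = 1, ORANGE = 5, PINK = 9)
  )
}

#' Default Schofield basal-metabolic-rate coefficients
#'
#' Age- and sex-banded linear predictors of BMR (kcal/day) from body weight
#' (kg), Schofield (1985). Adults only; the pipeline refuses ages under 18.
#'
#' @return Data frame with columns sex, age_min, age_max, a (kcal/kg), b (kcal).
#' @export
default_schofield_table <- function() {
  tibble::tribble(
    ~sex,     ~age_min, ~age_max, ~a,     ~b,
    "male",   18,       30,       15.057, 692.2,
    "male",   30,       60,       11.472, 873.1,
    "male",   60,       Inf,      11.711, 587.7,
    "female", 18,       30,       14.818, 486.6,
    "female", 30,       60,       8.126,  845.6,
    "female", 60,       Inf,      9.082,  658.5
  )
}

#' Default adequacy rules
#'
#' One rule per evaluated nutrient. `pct_energy` rules compare the percent
#' of total energy supplied by the nutrient (Atwater factors from the
#' config) against a band; `absolute` rules compare g/day; the `energy`
#' rule compares intake against a fraction of predicted expenditure
#' (strictly below). Defaults follow the French PNNS/ANSES framework for
#' lipids, carbohydrates, proteins, saturates, added sugars and fibre; they
#' are configuration, not printed constants, and should be overridden where
#' an authoritative table is available.
#'
#' @return Named list of rules.
#' @export
default_adequacy_rules <- function() {
  list(
    energy       = list(type = "energy", max_frac = 1.05),
    lipids       = list(type = "pct_energy", nutrient = "lipid_g",
                        atwater = "lipid", min = 35, max = 40),
    carbohydrates = list(type = "pct_energy", nutrient = "carb_g",
                        atwater = "carb", min = 40, max = 55),
    proteins     = list(type = "pct_energy", nutrient = "protein_g",
                        atwater = "protein", min = 10, max = 20),
    saturates    = list(type = "pct_energy", nutrient = "saturates_g",
                        atwater = "lipid", max = 12),
    added_sugars = list(type = "pct_energy", nutrient = "added_sugars_g",
                        atwater = "carb", max = 10),
    fibre        = list(type = "absolute", nutrient = "fibre_g", min = 25)
  )
}

#' Assemble the full pipeline configuration
#'
#' Returns the default configuration — point tables, class cut-offs, the
#' protein-gate rule, day weighting, Goldberg screening parameters, the
#' physical-activity-level map, Schofield coefficients, Atwater factors and
#' adequacy rules — with any element overridden by name. Overrides are
#' merged recursively, so `cnl_config(goldberg = list(cv_within_ei = 20))`
#' replaces one parameter and keeps the rest.
#'
#' @param ... Named overrides of configuration elements.
#' @return A list of class `cnl_config`.
#' @export
#' @examples
#' cfg <- cnl_config(goldberg = list(confidence = 0.90))
#' cfg$goldberg$confidence
cnl_config <- function(...) {
  cfg <- list(
    point_tables = default_point_tables(),
    class_cutoffs = default_class_cutoffs(),
    # Protein points are withheld when A-points reach the gate and fvln
    # points are below 5, unless the food is a cheese.
    protein_gate = list(a_threshold = 11, fvln_exempt_points = 5,
                        cheese_exempt = TRUE),
    day_weights = c(weekday = 5 / 7, weekend = 2 / 7),
    expected_records = c(weekday = 2, weekend = 1),
    goldberg = list(
      cv_within_ei = 23,   # % within-subject CV of energy intake
      cv_bmr = 8.5,        # % CV of BMR estimation
      cv_pal = 15,         # % CV of PAL
      days = 3,            # dietary record days
      n = 1,               # evaluated per individual
      confidence = 0.95,
      pal_source = "individual",  # or "population"
      population_pal = 1.55
    ),
    pal_map = c(low = 1.4, moderate = 1.6, high = 1.8),
    schofield = default_schofield_table(),
    atwater = c(carb = 4, protein = 4, lipid = 9, alcohol = 7),  # kcal/g
    adequacy_rules = default_adequacy_rules(),
    clustering = list(standardize = FALSE, hier_subsample = 1500,
                      kmeans_iter = 300, tol = 1e-8),
    substitution = list(fraction = 0.30, unit = "event")
  )
  overrides <- list(...)
  if (length(overrides)) {
    stopifnot(!is.null(names(overrides)), all(nzchar(names(overrides))))
    cfg <- utils::modifyList(cfg, overrides)
  }
  structure(cfg, class = "cnl_config")
}

#' Load a configuration from a YAML file
#'
#' Reads named overrides from YAML and merges them onto the defaults via
#' [cnl_config()]. Point tables in YAML are lists with `thresholds` and
#' `points`; Schofield coefficients a list of rows.
#'
#' @param path Path to a YAML file.
#' @return A `cnl_config` list.
#' @export
cnl_config_from_yaml <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  if (!is.null(raw$schofield)) {
    raw$schofield <- dplyr::bind_rows(lapply(raw$schofield, tibble::as_tibble))
  }
  do.call(cnl_config, raw)
}

#' Ordered 5-CNL colour levels, best to worst
#' @return Character vector GREEN, YELLOW, ORANGE, PINK, RED.
#' @export
cnl_colours <- function() c("GREEN", "YELLOW", "ORANGE", "PINK", "RED")

# internal: colour as ordered integer rank (GREEN = 1 ... RED = 5)
colour_rank <- function(colour) match(colour, cnl_colours())
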