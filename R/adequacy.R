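#' Energy adequacy of reported intake
#'
#' Reported energy intake is adequate when it is strictly below the
#' configured fraction (default 105%) of predicted expenditure
#' (Schofield BMR times the PAL multiplier).
#'
#' @param energy_intake Mean daily energy intake, kcal/d.
#' @param expenditure Predicted total energy expenditure, kcal/d.
#' @param config A [cnl_config()] list.
#' @return Logical vector.
#' @export
#' @examples
#' energy_adequacy(2000, 2000)   # TRUE:  100% of expenditure
#' energy_adequacy(2100, 2000)   # FALSE: exactly 105% is not adequate
energy_adequacy <- function(energy_intake, expenditure,
                            config = cnl_config()) {
  if (any(energy_intake < 0) || any(expenditure <= 0)) {
    stop("intake must be non-negative and expenditure positive")
  }
  max_frac <- config$adequacy_rules$energy$max_frac
  energy_intake < max_frac * expenditure
}

#' Evaluate nutrient adequacy of individual diets
#'
#' Applies the configured rule set to each person's daily intake:
#' percent-of-energy bands use the Atwater energy contribution of the
#' nutrient over total energy intake; absolute rules compare grams per
#' day; the energy rule compares intake with predicted expenditure.
#'
#' @param diets An `individual_diets` object (or its `nutrients` table).
#' @param persons Screened person table ([screen_underreporters()]) with
#'   `expenditure`; required only when an energy rule is evaluated.
#' @param rules Adequacy rule set (default from the config).
#' @param config A [cnl_config()] list.
#' @return Tibble: `person_id` plus one logical column per rule.
#' @export
evaluate_adequacy <- function(diets, persons = NULL, rules = NULL,
                              config = cnl_config()) {
  nutr <- if (inherits(diets, "individual_diets")) diets$nutrients else diets
  rules <- rules %||% config$adequacy_rules
  atw <- config$atwater
  out <- tibble::tibble(person_id = nutr$person_id)
  for (rule_name in names(rules)) {
    rule <- rules[[rule_name]]
    if (rule$type == "energy") {
      if (is.null(persons) || is.null(persons$expenditure)) {
        stop("energy rule needs a persons table with 'expenditure'")
      }
      exp_kcal <- persons$expenditure[match(nutr$person_id,
                                            persons$person_id)]
      if (anyNA(exp_kcal)) stop("missing expenditure for some persons")
      out[[rule_name]] <- energy_adequacy(nutr$energy_kcal, exp_kcal, config)
      next
    }
    if (is.null(nutr[[rule$nutrient]])) {
      stop("diet is missing nutrient '", rule$nutrient, "' needed by rule '",
           rule_name, "'")
    }
    value <- nutr[[rule$nutrient]]
    if (rule$type == "pct_energy") {
      value <- 100 * value * atw[[rule$atwater]] / nutr$energy_kcal
    } else if (rule$type != "absolute") {
      stop("unknown rule type: ", rule$type)
    }
    ok <- rep(TRUE, length(value))
    if (!is.null(rule$min)) ok <- ok & value >= rule$min
    if (!is.null(rule$max)) ok <- ok & value < rule$max
    out[[rule_name]] <- ok
  }
  out
}

#' Energy-adjust nutrient intakes by the residual method
#'
#' Regresses the nutrient on total energy intake across the population and
#' returns each person's residual plus the fitted value at the mean energy
#' intake — the classic residual adjustment used for descriptive intake
#' tables.
#'
#' @param nutrient Numeric vector of daily intakes.
#' @param energy Numeric vector of daily energy intakes (kcal/d).
#' @return Numeric vector of energy-adjusted intakes.
#' @export
energy_adjust <- function(nutrient, energy) {
  stopifnot(length(nutrient) == length(energy))
  if (length(unique(energy)) < 2) return(nutrient)
  fit <- stats::lm(nutrient ~ energy)
  unname(stats::residuals(fit)) +
    unname(stats::predict(fit, newdata = data.frame(energy = mean(energy))))
}

#' Population adequacy and intake summary by cluster and scenario
#'
#' Percentages of cluster members whose intake meets each rule, plus mean
#' and SD of (optionally energy-adjusted) daily nutrient intakes, for a
#' set of diet states (baseline and substitution scenarios).
#'
#' @param profiles Named list of adequacy tables ([evaluate_adequacy()]),
#'   one per diet state, e.g. `list(baseline = ..., S1 = ...)`.
#' @param clusters Tibble `person_id`, `cluster` (and optionally `label`).
#' @param diets Optional named list of `individual_diets` matching
#'   `profiles`, enabling the mean ± SD intake table.
#' @param adjust Energy-adjust the descriptive intake means (residual
#'   method, within diet state across all persons).
#' @return List with `adequacy` (cluster x scenario x rule, % adequate and
#'   n) and, when `diets` is given, `intakes` (cluster x scenario x
#'   nutrient mean/sd).
#' @export
population_summary <- function(profiles, clusters, diets = NULL,
                               adjust = TRUE) {
  stopifnot(is.list(profiles), length(profiles) > 0,
            !is.null(names(profiles)))
  empty <- setdiff(unique(clusters$cluster),
                   clusters$cluster[clusters$person_id %in%
                                      profiles[[1]]$person_id])
  if (length(empty)) warning("empty cluster(s) omitted: ",
                             paste(empty, collapse = ", "))
  adequacy <- dplyr::bind_rows(lapply(names(profiles), function(st) {
    prof <- dplyr::inner_join(profiles[[st]], clusters, by = "person_id")
    rule_cols <- setdiff(names(profiles[[st]]), "person_id")
    long <- tidyr::pivot_longer(prof, dplyr::all_of(rule_cols),
                                names_to = "rule", values_to = "adequate")
    out <- dplyr::summarise(
      dplyr::group_by(long, .data$cluster, .data$rule),
      pct_adequate = 100 * mean(.data$adequate),
      n = dplyr::n(), .groups = "drop")
    out$scenario <- st
    out
  }))

  intakes <- NULL
  if (!is.null(diets)) {
    intakes <- dplyr::bind_rows(lapply(names(diets), function(st) {
      nutr <- if (inherits(diets[[st]], "individual_diets")) {
        diets[[st]]$nutrients
      } else {
        diets[[st]]
      }
      val_cols <- intersect(.nutrient_cols, names(nutr))
      adj <- nutr
      if (adjust) {
        for (nc in setdiff(val_cols, "energy_kcal")) {
          adj[[nc]] <- energy_adjust(nutr[[nc]], nutr$energy_kcal)
        }
      }
      adj <- dplyr::inner_join(adj[, c("person_id", val_cols)], clusters,
                               by = "person_id")
      long <- tidyr::pivot_longer(adj, dplyr::all_of(val_cols),
                                  names_to = "nutrient")
      out <- dplyr::summarise(
        dplyr::group_by(long, .data$cluster, .data$nutrient),
        mean = mean(.data$value), sd = stats::sd(.data$value),
        .groups = "drop")
      out$scenario <- st
      out
    }))
  }
  list(adequacy = adequacy, intakes = intakes)
}
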