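# composition fields averaged when building a replacement (virtual) food
.comp_fields <- unique(c(.score_fields, .nutrient_cols))

# internal: substitution pool of a scored food table — non-alcoholic,
# grouped foods, split by class scale (beverages are never substituted by
# solid foods or vice versa)
substitution_pool <- function(foods) {
  stopifnot(!is.null(foods$colour), !is.null(foods$group_id))
  pool <- foods[!foods$is_alcoholic & !is.na(foods$group_id), , drop = FALSE]
  pool$scale <- ifelse(pool$category == "beverage", "beverage", "food")
  pool$rank <- colour_rank(pool$colour)
  pool
}

#' Mean composition of a group's foods in given colour classes
#'
#' Unweighted nutrient-wise arithmetic mean over the distinct member foods
#' of a food group whose colour lies in `classes` (alcoholic beverages are
#' never pooled). This is the composition attributed to a substituted food.
#'
#' @param foods Scored food table with `group_id` and `colour`.
#' @param group_id The food group.
#' @param classes Character vector of colour classes to pool.
#' @param scale `"food"` or `"beverage"`; only members on that class scale
#'   are pooled.
#' @return One-row tibble of composition fields, with attribute
#'   `n_sources`.
#' @export
class_mean_composition <- function(foods, group_id, classes,
                                   scale = "food") {
  pool <- substitution_pool(foods)
  members <- pool[pool$group_id == group_id & pool$scale == scale &
                    pool$colour %in% classes, , drop = FALSE]
  members <- dplyr::distinct(members, .data$food_id, .keep_all = TRUE)
  if (!nrow(members)) {
    stop("no substitution target in group '", group_id, "' for classes ",
         paste(classes, collapse = "/"))
  }
  out <- tibble::as_tibble(lapply(members[, .comp_fields], mean))
  attr(out, "n_sources") <- nrow(members)
  out
}

# internal: replacement compositions for every (group, scale, colour)
# combination that is substitutable under the scenario rule. Returns the
# virtual-food table (scored) plus the lookup keyed by group/scale/colour.
replacement_table <- function(foods, scenario, config = cnl_config()) {
  pool <- substitution_pool(foods)
  combos <- dplyr::distinct(pool, .data$group_id, .data$scale, .data$colour,
                            .data$rank)
  rows <- list()
  for (i in seq_len(nrow(combos))) {
    g <- combos$group_id[i]
    sc <- combos$scale[i]
    r <- combos$rank[i]
    present <- sort(unique(pool$rank[pool$group_id == g & pool$scale == sc]))
    better <- present[present < r]
    if (!length(better)) next  # already in the group's best class
    target_ranks <- if (scenario == "S1") better else max(better)
    target_classes <- cnl_colours()[target_ranks]
    comp <- class_mean_composition(foods, g, target_classes, sc)
    comp$food_id <- paste0("sub_", scenario, "_", g, "_", sc, "_",
                           tolower(combos$colour[i]))
    comp$group_id <- g
    # the blend is scored under the group's own category rules (e.g. the
    # added-fat ratio table, the cheese protein exemption)
    cats <- table(pool$category[pool$group_id == g & pool$scale == sc])
    comp$category <- names(cats)[which.max(cats)]
    comp$is_plain_water <- FALSE
    comp$is_unsweetened_hot_beverage <- FALSE
    comp$is_alcoholic <- FALSE
    comp$replaces_group <- g
    comp$replaces_scale <- sc
    comp$replaces_colour <- combos$colour[i]
    comp$target_classes <- paste(target_classes, collapse = "/")
    comp$source_worst_rank <- max(target_ranks)
    comp$n_sources <- attr(comp, "n_sources")
    rows[[length(rows) + 1L]] <- comp
  }
  if (!length(rows)) return(NULL)
  virt <- dplyr::bind_rows(rows)
  score_foods(virt, config)
}

# internal shared engine for the three scenarios
apply_substitution <- function(records, foods, scenario,
                               fraction = NULL, seed = NULL,
                               config = cnl_config()) {
  stopifnot(scenario %in% c("S1", "S2", "S3"))
  rule <- if (scenario == "S1") "S1" else "S2"
  virt <- replacement_table(foods, rule, config)

  ev <- records
  ev$.event <- seq_len(nrow(ev))
  info <- foods[, c("food_id", "group_id", "colour", "category",
                    "is_alcoholic")]
  ev <- dplyr::left_join(ev, info, by = "food_id")
  if (anyNA(ev$colour)) {
    stop("records contain foods absent from the scored food table")
  }
  ungrouped <- is.na(ev$group_id) & !ev$is_alcoholic
  if (any(ungrouped)) {
    message(sum(ungrouped), " event(s) reference ungrouped foods; ",
            "left unchanged")
  }
  ev$scale <- ifelse(ev$category == "beverage", "beverage", "food")
  if (is.null(virt)) {
    ev$replacement_id <- NA_character_
  } else {
    key <- virt[, c("replaces_group", "replaces_scale", "replaces_colour",
                    "food_id")]
    names(key) <- c("group_id", "scale", "colour", "replacement_id")
    ev <- dplyr::left_join(ev, key, by = c("group_id", "scale", "colour"))
  }
  ev$replacement_id[ev$is_alcoholic | is.na(ev$group_id)] <- NA_character_
  ev$eligible <- !is.na(ev$replacement_id)

  substitute_row <- ev$eligible
  if (scenario == "S3") {
    if (is.null(fraction) || fraction <= 0 || fraction > 1) {
      stop("scenario 3 needs a substitution fraction in (0, 1]")
    }
    if (is.null(seed)) stop("scenario 3 needs a seed")
    set.seed(seed)
    ord <- order(ev$person_id, ev$record_index, ev$.event)
    substitute_row <- rep(FALSE, nrow(ev))
    keys <- paste(ev$person_id, ev$record_index, sep = "\r")
    for (kk in unique(keys[ord])) {
      rows <- which(keys == kk & ev$eligible)
      m <- round(fraction * length(rows))
      if (m > 0) {
        chosen <- if (length(rows) == 1L) rows else
          sample(rows, m)
        substitute_row[chosen] <- TRUE
      }
    }
  }

  out_records <- records
  out_records$food_id[substitute_row] <- ev$replacement_id[substitute_row]
  ledger <- tibble::tibble(
    person_id = ev$person_id[substitute_row],
    record_index = ev$record_index[substitute_row],
    food_id = ev$food_id[substitute_row],
    quantity_g = ev$quantity_g[substitute_row],
    original_colour = ev$colour[substitute_row],
    group_id = ev$group_id[substitute_row],
    replacement_id = ev$replacement_id[substitute_row]
  )
  # findings: a pooled replacement whose re-scored class is worse than the
  # worst class that contributed to it (possible with nonlinear point
  # tables; reported, not an error)
  findings <- NULL
  if (!is.null(virt)) {
    bad <- colour_rank(virt$colour) > virt$source_worst_rank
    if (any(bad)) {
      findings <- virt[bad, c("food_id", "replaces_group", "replaces_colour",
                              "target_classes", "colour")]
      message(nrow(findings), " replacement composition(s) re-scored worse ",
              "than their worst source class")
    }
  }
  foods_aug <- if (is.null(virt)) {
    foods
  } else {
    dplyr::bind_rows(foods,
                     virt[, setdiff(names(virt),
                                    c("replaces_group", "replaces_scale",
                                      "replaces_colour", "target_classes",
                                      "source_worst_rank", "n_sources"))])
  }
  structure(list(scenario = scenario, records = out_records,
                 foods = foods_aug, ledger = ledger, findings = findings,
                 fraction = fraction, seed = seed,
                 n_events = nrow(records), n_eligible = sum(ev$eligible),
                 n_substituted = sum(substitute_row)),
            class = "scenario_result")
}

#' Scenario 1: substitute every food for the mean of all healthier classes
#'
#' Every consumption event whose food sits below the best colour class
#' present in its food group (on its own food/beverage scale) is given the
#' unweighted mean composition of all the group's foods in strictly better
#' classes; foods already in the group's best class, alcoholic beverages
#' and ungrouped foods are untouched. Quantities are always retained.
#'
#' @param records Event table `person_id`, `record_index`, `day_type`,
#'   `food_id`, `quantity_g`.
#' @param foods Scored food table with `group_id`.
#' @param config A [cnl_config()] list.
#' @return A `scenario_result`: modified `records`, augmented scored
#'   `foods` (original plus virtual replacement compositions), the
#'   substitution `ledger`, and counts.
#' @export
apply_scenario1 <- function(records, foods, config = cnl_config()) {
  apply_substitution(records, foods, "S1", config = config)
}

#' Scenario 2: substitute towards the adjacent better class
#'
#' As [apply_scenario1()], but the replacement is the mean composition of
#' the *nearest* strictly better non-empty colour class within the group
#' (stepping past empty classes).
#'
#' @inheritParams apply_scenario1
#' @return A `scenario_result`.
#' @export
apply_scenario2 <- function(records, foods, config = cnl_config()) {
  apply_substitution(records, foods, "S2", config = config)
}

#' Scenario 3: scenario 2 applied to a random fraction of foods
#'
#' Per 24-h record, a simple random sample of `round(fraction * n)` of the
#' scenario-2-eligible events receives the scenario-2 substitution; the
#' rest are untouched. Reproducible under `seed`.
#'
#' @inheritParams apply_scenario1
#' @param fraction Fraction of eligible events substituted per record
#'   (default 0.30).
#' @param seed Integer seed for the event sampling.
#' @return A `scenario_result`.
#' @export
apply_scenario3 <- function(records, foods, fraction = 0.30, seed = 1L,
                            config = cnl_config()) {
  apply_substitution(records, foods, "S3", fraction = fraction, seed = seed,
                     config = config)
}

#' Recompute individual intakes after substitution
#'
#' Re-runs the day-weighted intake computation over the scenario's
#' modified records and augmented food table (virtual replacement foods
#' carry their re-scored colour), so energy, colour energies and all
#' adequacy-relevant nutrients reflect the substituted compositions.
#'
#' @param result A `scenario_result`.
#' @param config A [cnl_config()] list.
#' @param record_meta Optional record metadata, as in
#'   [compute_daily_intakes()].
#' @return An `individual_diets` object.
#' @export
recompute_intakes <- function(result, config = cnl_config(),
                              record_meta = NULL) {
  stopifnot(inherits(result, "scenario_result"))
  compute_daily_intakes(result$records, result$foods, config,
                        record_meta = record_meta)
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf(
    "substitution scenario %s: %d of %d events substituted (%d eligible)\n",
    x$scenario, x$n_substituted, x$n_events, x$n_eligible))
  invisible(x)
}
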