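# Frequency levels L0..L5 correspond to: never; <1/week; 1-2/week; 3-6/week;
# 1/day; >=2/day. Cut points on weekly units and representative units per
# level are shipped with the score-table config.

wak_extdata <- function(...) {
  system.file("extdata", ..., package = "wakamola", mustWork = TRUE)
}

.wak_cache <- new.env(parent = emptyenv())

#' Canonical food items
#'
#' The 51 food-frequency items, each assigned to one of the 20 food groups
#' reported in the pilot and to an item class (daily / weekly / occasional
#' recommendation) that selects its penalty row. The list is configuration,
#' not code: supply your own CSV with the same columns to replace it.
#'
#' @param path CSV with columns item_id, group, item_class, label; default is
#'   the shipped list.
#' @return Data frame with one row per item.
#' @export
canonical_food_items <- function(path = NULL) {
  if (is.null(path)) {
    if (is.null(.wak_cache$items)) {
      .wak_cache$items <- utils::read.csv(wak_extdata("food_items.csv"),
                                          stringsAsFactors = FALSE)
    }
    return(.wak_cache$items)
  }
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Food groups of the canonical item list
#' @return Character vector of group ids.
#' @export
food_groups <- function() unique(canonical_food_items()$group)

#' Diet score table
#'
#' Maps every (food item, frequency level) pair to a penalty in [1, 10]
#' (higher = less healthy consumption) and carries the minimal and maximal
#' total penalty over complete diet records, used to normalize the diet score
#' onto 0-100.
#'
#' @param config Path to a JSON (or YAML, by extension) config with a
#'   \code{penalties} table by item class, or a parsed list of the same shape.
#'   Default: the shipped "default_v1".
#' @param items Canonical item data frame (see
#'   \code{\link{canonical_food_items}}).
#' @return Object of class \code{score_table}: penalty matrix (items x
#'   levels), P_min, P_max, level cut points and representative units.
#' @export
score_table <- function(config = NULL, items = canonical_food_items()) {
  cfg <- read_config(config, default = "score_table_default_v1.json")
  pen <- cfg$penalties
  classes <- unique(items$item_class)
  missing <- setdiff(classes, names(pen))
  if (length(missing))
    stop("score-table config lacks penalties for item class: ",
         paste(missing, collapse = ", "), call. = FALSE)
  mat <- t(vapply(items$item_class,
                  function(cl) as.numeric(unlist(pen[[cl]])),
                  numeric(length(FREQ_LEVELS))))
  dimnames(mat) <- list(items$item_id, FREQ_LEVELS)
  if (any(mat < 1 | mat > 10))
    stop("penalties must lie in [1, 10]", call. = FALSE)
  p_min <- sum(apply(mat, 1, min))
  p_max <- sum(apply(mat, 1, max))
  if (p_min >= p_max) stop("degenerate score table: P_min >= P_max", call. = FALSE)
  structure(list(
    name = if (!is.null(cfg$name)) cfg$name else "custom",
    penalty = mat, p_min = p_min, p_max = p_max,
    level_upper_bounds = as.numeric(unlist(lapply(cfg$level_upper_bounds,
                                                  function(x) if (is.null(x)) Inf else x))),
    level_representative_units = as.numeric(unlist(cfg$level_representative_units)),
    items = items
  ), class = "score_table")
}

#' @export
print.score_table <- function(x, ...) {
  cat("Diet score table '", x$name, "': ", nrow(x$penalty), " items, ",
      ncol(x$penalty), " levels, total penalty range [",
      x$p_min, ", ", x$p_max, "]\n", sep = "")
  invisible(x)
}

#' Scoring parameters
#'
#' Houses every tunable constant behind the sub-scores: IPAQ short-form MET
#' multipliers and the 180 min/day truncation, the MET-minute volume mapped
#' to activity score 100, the social-score mixture (degree weight and degree
#' saturation reference), the composite weights, and the fixed-point
#' stopping rule.
#'
#' @param met_vigorous,met_moderate,met_walk MET multipliers (IPAQ-SF
#'   protocol values 8.0 / 4.0 / 3.3).
#' @param daily_cap_minutes per-domain minutes truncated at this value
#'   (IPAQ-SF: 180).
#' @param activity_ref_met MET-min/week mapping to activity score 100.
#' @param social_degree_weight weight of the degree term in the social score,
#'   in [0, 1].
#' @param social_degree_ref contact count at which the degree term saturates.
#' @param wakastatus_weights named numeric (diet, activity, bmi, social),
#'   non-negative, summing to 1.
#' @param fixedpoint_tol,fixedpoint_max_iter stopping rule for the social /
#'   composite fixed point.
#' @return Object of class \code{scoring_params}.
#' @export
scoring_params <- function(met_vigorous = 8.0, met_moderate = 4.0,
                           met_walk = 3.3, daily_cap_minutes = 180,
                           activity_ref_met = 3000,
                           social_degree_weight = 0.5, social_degree_ref = 10,
                           wakastatus_weights = c(diet = 0.25, activity = 0.25,
                                                  bmi = 0.25, social = 0.25),
                           fixedpoint_tol = 1e-9, fixedpoint_max_iter = 1000) {
  w <- wakastatus_weights[c("diet", "activity", "bmi", "social")]
  if (anyNA(w) || any(w < 0) || abs(sum(w) - 1) > 1e-8)
    stop("wakastatus_weights must be named (diet, activity, bmi, social), non-negative and sum to 1",
         call. = FALSE)
  stopifnot(social_degree_weight >= 0, social_degree_weight <= 1,
            social_degree_ref > 0, fixedpoint_tol > 0,
            daily_cap_minutes > 0, activity_ref_met > 0,
            fixedpoint_max_iter >= 1)
  structure(list(
    met_vigorous = met_vigorous, met_moderate = met_moderate,
    met_walk = met_walk, daily_cap_minutes = daily_cap_minutes,
    activity_ref_met = activity_ref_met,
    social_degree_weight = social_degree_weight,
    social_degree_ref = social_degree_ref,
    wakastatus_weights = w,
    fixedpoint_tol = fixedpoint_tol,
    fixedpoint_max_iter = as.integer(fixedpoint_max_iter)
  ), class = "scoring_params")
}

#' Load scoring parameters from a config file
#'
#' @param config Path to JSON/YAML, parsed list, or NULL for the shipped
#'   "default_v1".
#' @return \code{scoring_params}.
#' @export
read_scoring_params <- function(config = NULL) {
  cfg <- read_config(config, default = "params_default_v1.json")
  scoring_params(
    met_vigorous = cfg$met_vigorous, met_moderate = cfg$met_moderate,
    met_walk = cfg$met_walk, daily_cap_minutes = cfg$daily_cap_minutes,
    activity_ref_met = cfg$activity_ref_met,
    social_degree_weight = cfg$social_degree_weight,
    social_degree_ref = cfg$social_degree_ref,
    wakastatus_weights = unlist(cfg$wakastatus_weights),
    fixedpoint_tol = cfg$fixedpoint_tol,
    fixedpoint_max_iter = cfg$fixedpoint_max_iter
  )
}

# Reads a config given as a parsed list, a .json path, a .yml/.yaml path, or
# NULL (shipped default under extdata).
read_config <- function(config, default) {
  if (is.null(config)) config <- wak_extdata(default)
  if (is.list(config)) return(config)
  ext <- tolower(tools::file_ext(config))
  if (ext %in% c("yml", "yaml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("package 'yaml' is required to read YAML configs", call. = FALSE)
    yaml::read_yaml(config)
  } else {
    jsonlite::read_json(config, simplifyVector = FALSE)
  }
}

#' Convert weekly consumption units to a frequency level
#'
#' Deterministic binning by the documented cut points: 0 -> L0; (0,1) -> L1;
#' [1,3) -> L2; [3,7) -> L3; [7,14) -> L4; >= 14 -> L5.
#'
#' @param units weekly consumption units (vectorised, non-negative).
#' @param table \code{score_table} carrying the cut points.
#' @return Character vector of levels "L0".."L5".
#' @export
units_to_level <- function(units, table = score_table()) {
  stopifnot(all(units >= 0))
  ub <- table$level_upper_bounds   # upper bound of each level, last Inf
  idx <- vapply(units, function(u) {
    if (u == 0) return(1L)
    which(u < ub | (is.infinite(ub) & u >= 14))[1]
  }, integer(1))
  FREQ_LEVELS[idx]
}

#' Representative weekly units for a frequency level
#'
#' Inverse of \code{\link{units_to_level}} used when summarizing diets:
#' L0..L5 -> 0, 0.5, 2, 4.5, 9, 16 units/week.
#'
#' @param level character vector of levels "L0".."L5".
#' @param table \code{score_table} carrying the representatives.
#' @return Numeric vector of weekly units.
#' @export
level_to_units <- function(level, table = score_table()) {
  idx <- match(level, FREQ_LEVELS)
  if (anyNA(idx)) stop("unknown frequency level", call. = FALSE)
  table$level_representative_units[idx]
}
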