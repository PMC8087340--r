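# Cohort report: BMI-category prevalence, score summaries, food-group and
# activity tables, network summary. Percentages are half-up to one decimal;
# dispersions are population SDs (footnoted in the text report).

sd_pop <- function(x) sqrt(mean((x - mean(x))^2))

#' BMI-category prevalence of a scored roster
#'
#' @param scorecards data frame from \code{\link{compute_scorecards}}.
#' @return Data frame: bmi_category, count, pct (one decimal, half-up).
#' @export
bmi_prevalence <- function(scorecards) {
  lev <- c("underweight", "normal", "overweight", "obesity1", "obesity2",
           "obesity3")
  counts <- table(factor(scorecards$bmi_category, levels = lev))
  data.frame(bmi_category = lev, count = as.integer(counts),
             pct = round_half_up(100 * as.integer(counts) / nrow(scorecards), 1),
             stringsAsFactors = FALSE)
}

#' Mean and population SD of the five scores and BMI
#' @param scorecards scorecard data frame.
#' @return Data frame: variable, mean, sd.
#' @export
score_summary <- function(scorecards) {
  vars <- c("bmi", "diet_score", "activity_score", "bmi_score",
            "social_score", "wakastatus", "met_minutes")
  data.frame(variable = vars,
             mean = vapply(vars, function(v) mean(scorecards[[v]]), numeric(1)),
             sd = vapply(vars, function(v) sd_pop(scorecards[[v]]), numeric(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Food-group weekly consumption means of a cohort
#'
#' Maps each answered frequency level to its representative weekly units and
#' averages by food group over completed participants; rows sorted ascending
#' by mean (the printed table's ordering).
#'
#' @param cohort \code{cohort}.
#' @param table \code{score_table}.
#' @return Data frame: group, mean_units_week.
#' @export
food_group_means <- function(cohort, table = score_table()) {
  ids <- completed_ids(cohort)
  items <- table$items
  groups <- unique(items$group)
  per_user <- vapply(ids, function(uid) {
    ans <- cohort$assessments[[uid]]$diet$answers
    units <- level_to_units(ans[items$item_id], table)
    vapply(split(units, items$group)[groups], sum, numeric(1))
  }, numeric(length(groups)))
  m <- if (length(ids) == 1) per_user else rowMeans(per_user)
  out <- data.frame(group = groups, mean_units_week = as.numeric(m),
                    stringsAsFactors = FALSE)
  out[order(out$mean_units_week), , drop = FALSE]
}

#' Activity and sleep means of a cohort
#' @param cohort \code{cohort}.
#' @return Data frame: variable, mean (activity fields plus sleep hours).
#' @export
activity_means <- function(cohort) {
  ids <- completed_ids(cohort)
  acts <- lapply(ids, function(uid) cohort$assessments[[uid]]$activity)
  fields <- ACTIVITY_NUM
  means <- vapply(fields, function(f)
    mean(vapply(acts, `[[`, numeric(1), f)), numeric(1))
  sleep <- mean(vapply(ids, function(uid)
    cohort$assessments[[uid]]$personal$sleep_hours, numeric(1)))
  data.frame(variable = c(fields, "sleep_hours"),
             mean = c(unname(means), sleep), stringsAsFactors = FALSE)
}

#' Full cohort report
#'
#' @param cohort \code{cohort}.
#' @param scorecards scorecard data frame for its completers.
#' @param seed seed for community detection (default 0).
#' @param table \code{score_table}.
#' @return List: n, bmi_prevalence, score_summary, food_groups, activity,
#'   network (see \code{\link{network_summary}}).
#' @export
cohort_report <- function(cohort, scorecards, seed = 0,
                          table = score_table()) {
  g <- build_graph(cohort, scorecards)
  part <- detect_communities(g, seed = seed)
  list(n = nrow(scorecards),
       bmi_prevalence = bmi_prevalence(scorecards),
       score_summary = score_summary(scorecards),
       food_groups = food_group_means(cohort, table),
       activity = activity_means(cohort),
       network = network_summary(g, part))
}

format_report_text <- function(rep) {
  w <- function(...) paste0(..., collapse = "")
  lines <- c(
    sprintf("Cohort report (n = %d completers)", rep$n),
    "",
    "BMI categories:",
    sprintf("  %-12s %4d  %5.1f%%", rep$bmi_prevalence$bmi_category,
            rep$bmi_prevalence$count, rep$bmi_prevalence$pct),
    "",
    "Scores (mean, SD):",
    sprintf("  %-16s %8.2f %8.2f", rep$score_summary$variable,
            rep$score_summary$mean, rep$score_summary$sd),
    "",
    "Food groups (units/week, ascending):",
    sprintf("  %-16s %6.2f", rep$food_groups$group,
            rep$food_groups$mean_units_week),
    "",
    "Activity and sleep (means):",
    sprintf("  %-18s %8.2f", rep$activity$variable, rep$activity$mean),
    "",
    sprintf("Network: %d nodes, %d edges, %d isolated, %d communities (%d with >1 member), largest %d",
            rep$network$n_nodes, rep$network$n_edges, rep$network$n_isolated,
            rep$network$n_communities, rep$network$n_communities_multi,
            rep$network$largest_community_size),
    "",
    "Note: dispersions are population SDs; percentages round half-up to 1 decimal."
  )
  paste(lines, collapse = "\n")
}
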