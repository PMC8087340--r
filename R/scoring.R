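#' BMI sub-score (WakaBMI)
#'
#' Five-level step function of BMI category: 100 points for normal weight
#' (18.5-24.9), 75 for overweight (25-29.9) or underweight (<18.5), 50 for
#' obesity class 1 (30-34.9), 25 for class 2 (35-39.9), 0 for extreme
#' obesity class 3 (>= 40).
#'
#' @param bmi BMI in kg/m^2 (vectorised).
#' @return Points in \{100, 75, 50, 25, 0\}.
#' @export
score_bmi <- function(bmi) {
  cat <- bmi_category(bmi)
  unname(c(underweight = 75, normal = 100, overweight = 75,
           obesity1 = 50, obesity2 = 25, obesity3 = 0)[as.character(cat)])
}

#' Diet sub-score (Wakalimentation)
#'
#' Sums the per-item penalties for the answered frequency levels and maps the
#' total S affinely onto 0-100: \code{100 * (P_max - S) / (P_max - P_min)}.
#' The inversion makes the score "higher = healthier" while item penalties
#' grow with unhealthiness.
#'
#' @param diet complete \code{diet_record}.
#' @param table \code{score_table}.
#' @return Score in [0, 100].
#' @export
score_diet <- function(diet, table = score_table()) {
  ans <- diet$answers
  item_ids <- rownames(table$penalty)
  missing <- setdiff(item_ids, names(ans))
  if (length(missing))
    stop("diet record incomplete: ", length(missing), " items unanswered (e.g. ",
         missing[1], ")", call. = FALSE)
  unknown <- setdiff(names(ans), item_ids)
  if (length(unknown))
    stop("food item not in score table: ", unknown[1], call. = FALSE)
  lev <- match(ans[item_ids], FREQ_LEVELS)
  if (anyNA(lev)) stop("invalid frequency level in diet record", call. = FALSE)
  s <- sum(table$penalty[cbind(seq_along(item_ids), lev)])
  100 * (table$p_max - s) / (table$p_max - table$p_min)
}

#' IPAQ short-form MET-minutes per week
#'
#' Weekly physical-activity volume with per-domain session minutes truncated
#' at \code{daily_cap_minutes} (IPAQ-SF protocol: 180):
#' \code{8.0*v_days*min(v_min,cap) + 4.0*m_days*min(m_min,cap) +
#' 3.3*w_days*min(w_min,cap)}.
#'
#' @param activity \code{activity_record}.
#' @param params \code{scoring_params}.
#' @return MET-minutes/week, non-negative.
#' @export
ipaq_met_minutes <- function(activity, params = scoring_params()) {
  cap <- params$daily_cap_minutes
  params$met_vigorous * activity$vigorous_days * min(activity$vigorous_minutes, cap) +
    params$met_moderate * activity$moderate_days * min(activity$moderate_minutes, cap) +
    params$met_walk * activity$walk_days * min(activity$walk_minutes, cap)
}

#' Activity sub-score
#'
#' Linear in MET-minutes/week with saturation at \code{activity_ref_met}
#' (default 3000, the conventional high-activity threshold):
#' \code{100 * min(met_minutes / activity_ref_met, 1)}.
#'
#' @param activity \code{activity_record}.
#' @param params \code{scoring_params}.
#' @return Score in [0, 100].
#' @export
score_activity <- function(activity, params = scoring_params()) {
  100 * min(ipaq_met_minutes(activity, params) / params$activity_ref_met, 1)
}

#' Score a cohort: the four sub-scores and the composite Wakastatus
#'
#' For each completed participant i with degree d_i and neighbours N(i) in
#' the relation graph,
#' \deqn{Social_i = 100 [ w_{deg} \min(d_i/D_{ref}, 1) + (1 - w_{deg})
#'   \overline{W}_{N(i)} / 100 ]}
#' (the neighbour-mean term is 0 when N(i) is empty), and
#' \deqn{W_i = \sum_k w_k S_{ik}} over the four sub-scores. Because the
#' social score depends on neighbours' composite scores, the coupled system
#' is solved by Jacobi fixed-point iteration from Social = 0 until the
#' maximal absolute change falls below \code{fixedpoint_tol}. The iteration
#' is a linear contraction with coefficient
#' \code{(1 - w_deg) * weight_social} (< 1 under any valid parameters with
#' w_deg > 0 or weight_social < 1), so it converges from any start.
#'
#' Participants with incomplete sections are excluded (the pilot's filtering
#' rule); their ids are attached as attribute \code{"excluded"}. Relations
#' touching excluded users are ignored for scoring.
#'
#' @param cohort \code{cohort}.
#' @param table \code{score_table}.
#' @param params \code{scoring_params}.
#' @return Data frame (one row per completed participant): user_id, bmi,
#'   bmi_category, diet_score, activity_score, bmi_score, social_score,
#'   wakastatus, met_minutes, converged, iterations. Attributes: "excluded"
#'   (ids not scored), "iterations", "converged".
#' @export
compute_scorecards <- function(cohort, table = score_table(),
                               params = scoring_params()) {
  ids <- completed_ids(cohort)
  all_ids <- vapply(cohort$assessments, function(a) a$user_id, character(1))
  excluded <- setdiff(all_ids, ids)
  n <- length(ids)
  if (n == 0) {
    out <- data.frame(user_id = character(), bmi = numeric(),
                      bmi_category = character(), diet_score = numeric(),
                      activity_score = numeric(), bmi_score = numeric(),
                      social_score = numeric(), wakastatus = numeric(),
                      met_minutes = numeric(), converged = logical(),
                      iterations = integer(), stringsAsFactors = FALSE)
    attr(out, "excluded") <- excluded
    return(out)
  }

  bmi <- diet <- act <- met <- numeric(n)
  for (k in seq_len(n)) {
    a <- cohort$assessments[[ids[k]]]
    bmi[k] <- compute_bmi(a$personal$weight, a$personal$height)
    diet[k] <- score_diet(a$diet, table)
    met[k] <- ipaq_met_minutes(a$activity, params)
    act[k] <- score_activity(a$activity, params)
  }
  bmi_sc <- score_bmi(bmi)

  # adjacency among completers (undirected, typed duplicates collapse)
  nbrs <- rep(list(integer(0)), n)
  names(nbrs) <- ids
  seen <- character(0)
  for (r in cohort$relations) {
    if (!(r$user_a %in% ids) || !(r$user_b %in% ids)) next
    key <- paste(r$user_a, r$user_b, sep = "\r")
    if (key %in% seen) next
    seen <- c(seen, key)
    ia <- match(r$user_a, ids); ib <- match(r$user_b, ids)
    nbrs[[ia]] <- c(nbrs[[ia]], ib)
    nbrs[[ib]] <- c(nbrs[[ib]], ia)
  }
  deg <- lengths(nbrs)

  fp <- solve_social_fixedpoint(diet, act, bmi_sc, nbrs, deg, params)

  out <- data.frame(
    user_id = ids, bmi = bmi, bmi_category = as.character(bmi_category(bmi)),
    diet_score = diet, activity_score = act, bmi_score = bmi_sc,
    social_score = fp$social, wakastatus = fp$wakastatus,
    met_minutes = met, converged = fp$converged, iterations = fp$iterations,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  attr(out, "iterations") <- fp$iterations
  attr(out, "converged") <- fp$converged
  out
}

# Jacobi iteration for the coupled social/composite scores. Exposed to tests
# via wakamola:::solve_social_fixedpoint for oracle comparisons.
solve_social_fixedpoint <- function(diet, act, bmi_sc, nbrs, deg, params,
                                    social0 = rep(0, length(diet))) {
  w <- params$wakastatus_weights
  wd <- params$social_degree_weight
  dref <- params$social_degree_ref
  fixed_part <- w[["diet"]] * diet + w[["activity"]] * act + w[["bmi"]] * bmi_sc
  deg_term <- 100 * wd * pmin(deg / dref, 1)
  social <- social0
  waka <- fixed_part + w[["social"]] * social
  it <- 0L
  converged <- FALSE
  while (it < params$fixedpoint_max_iter) {
    it <- it + 1L
    nbr_mean <- vapply(seq_along(nbrs), function(i) {
      if (deg[i] == 0) 0 else mean(waka[nbrs[[i]]])
    }, numeric(1))
    social_new <- deg_term + (1 - wd) * nbr_mean
    delta <- max(abs(social_new - social), 0)
    social <- social_new
    waka <- fixed_part + w[["social"]] * social
    if (delta < params$fixedpoint_tol) { converged <- TRUE; break }
  }
  if (!converged)
    stop(sprintf("social-score fixed point did not converge in %d iterations (last residual %.3g)",
                 params$fixedpoint_max_iter, delta), call. = FALSE)
  list(social = social, wakastatus = waka, iterations = it,
       converged = converged)
}

#' Write scorecards to CSV
#'
#' Emits the documented scores.csv schema: user_id, bmi, bmi_category,
#' diet_score, activity_score, bmi_score, social_score, wakastatus,
#' met_minutes, converged, iterations.
#'
#' @param scorecards output of \code{\link{compute_scorecards}}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_scores_csv <- function(scorecards, path) {
  utils::write.csv(scorecards, path, row.names = FALSE)
  invisible(path)
}

#' Read a scores.csv written by \code{\link{write_scores_csv}}
#' @param path CSV file.
#' @return Scorecard data frame.
#' @export
read_scores_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(user_id = "character"))
}
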