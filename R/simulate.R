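# Synthetic-cohort simulator. The shipped "pilot2019" profile encodes the
# published statistics of the university pilot (n = 74, BMI mean 21.4 SD
# 2.41, food-group weekly means, activity and sleep means, 178 expected
# relations over 12 planted blocks with 5/74 isolated users) so every other
# module can be exercised at desk scale without any real data.

#' Simulator profile
#'
#' Parameter set for \code{\link{generate_cohort}} and the per-section
#' generators. Load the shipped pilot-calibrated default with
#' \code{\link{pilot2019_profile}} or supply a JSON/YAML file of the same
#' shape.
#'
#' @param config parsed list or path to a JSON/YAML profile.
#' @return Object of class \code{sim_profile}.
#' @export
sim_profile <- function(config) {
  p <- read_config(config, default = file.path("profiles", "pilot2019.json"))
  stopifnot(p$n >= 0, p$female_fraction >= 0, p$female_fraction <= 1,
            p$bmi$sd >= 0, p$bmi$lower < p$bmi$upper,
            p$network$isolated_fraction >= 0,
            p$network$isolated_fraction <= 1,
            p$network$within_prob >= 0, p$network$within_prob <= 1)
  p$food_weekly_means <- unlist(p$food_weekly_means)
  p$activity <- lapply(p$activity, as.numeric)
  structure(p, class = "sim_profile")
}

#' The pilot-calibrated simulator profile
#' @return \code{sim_profile} named "pilot2019".
#' @export
pilot2019_profile <- function() {
  sim_profile(wak_extdata("profiles", "pilot2019.json"))
}

#' @export
print.sim_profile <- function(x, ...) {
  cat("Simulator profile '", x$name, "': n = ", x$n,
      ", BMI ~ truncN(", x$bmi$mean, ", ", x$bmi$sd, ") on [",
      x$bmi$lower, ", ", x$bmi$upper, "], ",
      x$network$n_blocks, " network blocks\n", sep = "")
  invisible(x)
}

# Truncated-normal sampling by inverse CDF; exact, no rejection. sd = 0
# degenerates to the (clamped) mean.
rtruncnorm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  if (sd == 0) return(rep(min(max(mean, lo), hi), n))
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

# Mean of the truncated normal, for Monte-Carlo oracles.
truncnorm_mean <- function(mean, sd, lo, hi) {
  if (sd == 0) return(min(max(mean, lo), hi))
  a <- (lo - mean) / sd; b <- (hi - mean) / sd
  mean + sd * (stats::dnorm(a) - stats::dnorm(b)) /
    (stats::pnorm(b) - stats::pnorm(a))
}

with_seed_if <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(as.integer(seed), code)
}

#' Generate personal-section records
#'
#' BMI is drawn directly from a truncated normal on the profile bounds,
#' height from a gender-conditional normal, and weight derived as
#' \code{bmi * height^2}, so the generated BMI distribution matches the
#' profile exactly. Disease flags are Bernoulli at the profile prevalence
#' (0 under "pilot2019").
#'
#' @param profile \code{sim_profile}.
#' @param n number of records.
#' @param seed optional RNG seed for reproducibility.
#' @return List of \code{personal_record}.
#' @export
generate_personal <- function(profile, n = 1, seed = NULL) {
  if (n == 0) return(list())
  with_seed_if(seed, {
    gender <- ifelse(stats::runif(n) < profile$female_fraction,
                     "female", "male")
    hpar <- profile$height
    height <- vapply(gender, function(g)
      rtruncnorm(1, hpar[[g]]$mean, hpar[[g]]$sd, 1.3, 2.2), numeric(1))
    bmi <- rtruncnorm(n, profile$bmi$mean, profile$bmi$sd,
                      profile$bmi$lower, profile$bmi$upper)
    weight <- bmi * height^2
    age <- rtruncnorm(n, profile$age$mean, profile$age$sd, 14, 110)
    sleep <- rtruncnorm(n, profile$sleep$mean, profile$sleep$sd, 0, 24)
    cigarettes <- stats::rpois(n, profile$cigarettes_mean)
    dx <- matrix(stats::runif(4 * n) < profile$disease_prevalence, ncol = 4)
    edu <- sample(c("primary", "secondary", "university", "postgraduate"),
                  n, replace = TRUE, prob = c(.05, .25, .6, .1))
    marital <- sample(c("single", "partner", "married", "other"),
                      n, replace = TRUE, prob = c(.7, .15, .1, .05))
    mainact <- sample(MAIN_ACTIVITIES, n, replace = TRUE,
                      prob = c(.75, .2, .05))
    zips <- sprintf("46%03d", sample.int(profile$n_zip_areas, n,
                                         replace = TRUE) - 1L)
    household <- 1L + stats::rpois(n, 2)
    lapply(seq_len(n), function(i) personal_record(
      weight = weight[i], height = height[i], gender = gender[i],
      age = age[i], education_level = edu[i], marital_status = marital[i],
      household_size = household[i], main_activity = mainact[i],
      zip_code = zips[i], sleep_hours = sleep[i], cigarettes = cigarettes[i],
      dx_hypertension = dx[i, 1], dx_diabetes = dx[i, 2],
      dx_cholesterol = dx[i, 3], dx_cardiovascular = dx[i, 4]))
  })
}

# Stochastic rounding of a continuous weekly amount onto the representative
# grid (0, 0.5, 2, 4.5, 9, 16): pick the upper bracketing level with
# probability proportional to the position inside the bracket, so
# E[representative | amount] = amount and group-mean recovery is unbiased.
stochastic_level <- function(u, reps) {
  k <- length(reps)
  idx <- vapply(u, function(x) {
    if (x <= reps[1]) return(1L)
    if (x >= reps[k]) return(k)
    j <- findInterval(x, reps)         # reps[j] <= x < reps[j+1]
    p_up <- (x - reps[j]) / (reps[j + 1] - reps[j])
    if (stats::runif(1) < p_up) j + 1L else j
  }, integer(1))
  FREQ_LEVELS[idx]
}

#' Generate diet-section records
#'
#' Per-item weekly amounts are continuous scaled-Beta draws on [0, 16] with
#' mean equal to the group mean split evenly over the group's items;
#' frequency levels are assigned by stochastic rounding onto the
#' level-representative grid, which makes the recovered group means (via
#' \code{\link{level_to_units}}) unbiased for every configured mean.
#'
#' @param profile \code{sim_profile} (uses \code{food_weekly_means}).
#' @param n number of records.
#' @param seed optional RNG seed.
#' @param table \code{score_table} carrying the representative grid.
#' @return List of \code{diet_record}.
#' @export
generate_diet <- function(profile, n = 1, seed = NULL, table = score_table()) {
  items <- table$items
  reps <- table$level_representative_units
  hi <- reps[length(reps)]
  group_n <- table(items$group)
  item_mean <- profile$food_weekly_means[items$group] /
    as.numeric(group_n[items$group])
  if (anyNA(item_mean))
    stop("profile lacks a weekly mean for food group: ",
         paste(setdiff(items$group, names(profile$food_weekly_means)),
               collapse = ", "), call. = FALSE)
  conc <- 2  # beta concentration: dispersed, strictly inside (0, hi)
  with_seed_if(seed, {
    lapply(seq_len(n), function(i) {
      u <- vapply(item_mean, function(m) {
        if (m <= 0) return(0)
        if (m >= hi) return(hi)
        hi * stats::rbeta(1, conc * m / hi, conc * (1 - m / hi))
      }, numeric(1))
      lev <- stochastic_level(u, reps)
      diet_record(setNames(lev, items$item_id))
    })
  })
}

#' Generate activity-section records
#'
#' Day counts are Binomial(7, mean/7) — a bounded count model whose mean is
#' exactly the configured mean on the native 0..7 support; session minutes
#' and weekly sitting hours are gamma with the configured mean.
#'
#' @param profile \code{sim_profile} (uses \code{activity}).
#' @param n number of records.
#' @param seed optional RNG seed.
#' @return List of \code{activity_record}.
#' @export
generate_activity <- function(profile, n = 1, seed = NULL) {
  a <- profile$activity
  rdays <- function(m) stats::rbinom(n, 7, m / 7)
  rmins <- function(m) if (m == 0) rep(0, n) else
    pmin(stats::rgamma(n, shape = 2, scale = m / 2), 960)
  with_seed_if(seed, {
    vd <- rdays(a$vigorous_days); vm <- rmins(a$vigorous_minutes)
    md <- rdays(a$moderate_days); mm <- rmins(a$moderate_minutes)
    wd <- rdays(a$walk_days);     wm <- rmins(a$walk_minutes)
    sit <- if (a$sitting_hours == 0) rep(0, n) else
      pmin(stats::rgamma(n, shape = 4, scale = a$sitting_hours / 4), 168)
    lapply(seq_len(n), function(i) activity_record(
      vigorous_days = vd[i], vigorous_minutes = vm[i],
      moderate_days = md[i], moderate_minutes = mm[i],
      walk_days = wd[i], walk_minutes = wm[i], sitting_hours = sit[i]))
  })
}

#' Generate typed relations with planted community structure
#'
#' Non-isolated users are dealt into the configured number of blocks; each
#' within-block pair is an edge with probability \code{within_prob} and each
#' between-block pair with \code{between_prob}. When \code{between_prob} is
#' NULL it is calibrated so the expected edge count equals
#' \code{n * mean_degree / 2}. Relation types are drawn from the profile's
#' type probabilities.
#'
#' @param profile \code{sim_profile} (uses \code{network}).
#' @param user_ids character ids; length must equal \code{profile$n}.
#' @param seed optional RNG seed.
#' @return List of \code{relation}.
#' @export
generate_network <- function(profile, user_ids, seed = NULL) {
  net <- profile$network
  n <- length(user_ids)
  if (n != profile$n)
    stop("length(user_ids) must equal profile n (", profile$n, ")", call. = FALSE)
  if (n < 2) return(list())
  with_seed_if(seed, {
    n_iso <- round(net$isolated_fraction * n)
    shuffled <- sample(user_ids)
    linked <- shuffled[seq_len(n - n_iso)]
    m <- length(linked)
    if (m < 2) {
      list()
    } else {
      nb <- min(net$n_blocks, m)
      block <- rep_len(seq_len(nb), m)          # balanced deal
      sizes <- tabulate(block, nb)
      within_pairs <- sum(choose(sizes, 2))
      total_pairs <- choose(m, 2)
      between_pairs <- total_pairs - within_pairs
      p_in <- net$within_prob
      p_out <- net$between_prob
      if (is.null(p_out)) {
        target <- profile$n * net$mean_degree / 2
        p_out <- if (between_pairs > 0)
          max(0, min(1, (target - p_in * within_pairs) / between_pairs)) else 0
      }
      pr <- t(utils::combn(m, 2))
      same <- block[pr[, 1]] == block[pr[, 2]]
      keep <- stats::runif(nrow(pr)) < ifelse(same, p_in, p_out)
      pr <- pr[keep, , drop = FALSE]
      tp <- net$type_probs
      types <- sample(names(tp), nrow(pr), replace = TRUE,
                      prob = as.numeric(unlist(tp)))
      lapply(seq_len(nrow(pr)), function(i)
        relation(linked[pr[i, 1]], linked[pr[i, 2]], types[i]))
    }
  })
}

#' Generate a complete synthetic cohort
#'
#' Streams one sub-seed per section from the master seed so sections are
#' independently reproducible; the result is validation-clean by
#' construction.
#'
#' @param profile \code{sim_profile}.
#' @param seed master RNG seed (default: the profile's).
#' @param n participant count (default: the profile's).
#' @return \code{cohort}.
#' @export
generate_cohort <- function(profile, seed = profile$seed, n = profile$n) {
  sub <- withr::with_seed(as.integer(seed),
                          sample.int(.Machine$integer.max - 1L, 4))
  ids <- if (n > 0) sprintf("u%03d", seq_len(n)) else character(0)
  pers <- generate_personal(profile, n, seed = sub[1])
  diets <- generate_diet(profile, n, seed = sub[2])
  acts <- generate_activity(profile, n, seed = sub[3])
  prof_n <- profile
  prof_n$n <- n
  rels <- generate_network(prof_n, ids, seed = sub[4])
  items <- canonical_food_items()$item_id
  assessments <- lapply(seq_len(n), function(i)
    assessment(ids[i], personal = pers[[i]], diet = diets[[i]],
               activity = acts[[i]], language = "es", items = items))
  cohort(assessments, rels)
}
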