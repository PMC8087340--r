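test_that("BMI sub-score reproduces the five printed point values", {
  expect_identical(score_bmi(21.2), 100)
  expect_identical(score_bmi(27), 75)
  expect_identical(score_bmi(17), 75)
  expect_identical(score_bmi(33.0), 50)
  expect_identical(score_bmi(37.0), 25)
  expect_identical(score_bmi(40.0), 0)
})

test_that("BMI sub-score is the exact step function of the category over a fine grid", {
  grid <- seq(10, 60, by = 0.01)
  pts <- score_bmi(grid)
  expected <- c(underweight = 75, normal = 100, overweight = 75,
                obesity1 = 50, obesity2 = 25, obesity3 = 0)
  expect_equal(pts, unname(expected[as.character(bmi_category(grid))]))
})

test_that("diet score normalization endpoints and toy-table value", {
  tab <- score_table()
  expect_equal(score_diet(diet_record(best_diet_answers()), tab), 100)
  expect_equal(score_diet(diet_record(worst_diet_answers()), tab), 0)

  toy <- toy_score_table()
  expect_equal(toy$p_min, 3)
  expect_equal(toy$p_max, 30)
  # penalties 10 + 2 + 2 = 14 -> 100 * (30 - 14) / 27
  d <- diet_record(c(a = "L5", b = "L1", c = "L1"))
  expect_equal(score_diet(d, toy), 100 * 16 / 27)
})

test_that("diet score errors on incomplete or unknown items", {
  tab <- toy_score_table()
  expect_error(score_diet(diet_record(c(a = "L0", b = "L0")), tab),
               "incomplete")
  expect_error(score_diet(diet_record(c(a = "L0", b = "L0", c = "L0",
                                        z = "L0")), tab), "z")
})

test_that("diet score is monotonically non-increasing in any single item's penalty", {
  tab <- score_table()
  items <- canonical_food_items()
  base <- best_diet_answers()
  for (k in c(1, 25, 51)) {
    id <- items$item_id[k]
    pen <- tab$penalty[id, ]
    ord <- names(sort(pen))             # levels by increasing penalty
    scores <- vapply(ord, function(lv) {
      d <- base; d[id] <- lv
      score_diet(diet_record(d), tab)
    }, numeric(1))
    expect_true(all(diff(scores) <= 1e-12))
  }
})

test_that("IPAQ MET-minutes match the protocol arithmetic and cap", {
  expect_equal(ipaq_met_minutes(activity_record()), 0)
  a <- activity_record(3, 30, 2, 30, 5, 30)
  expect_equal(ipaq_met_minutes(a), 8 * 90 + 4 * 60 + 3.3 * 150)  # 1455
  capped <- activity_record(vigorous_days = 1, vigorous_minutes = 500)
  expect_equal(ipaq_met_minutes(capped), 8 * 180)                  # 1440
})

test_that("IPAQ MET-minutes are monotone in each field and cap-invariant below it", {
  base <- activity_record(2, 40, 2, 40, 2, 40, 10)
  for (f in c("vigorous_days", "vigorous_minutes", "moderate_days",
              "moderate_minutes", "walk_days", "walk_minutes")) {
    up <- base
    up[[f]] <- up[[f]] + 1
    expect_gte(ipaq_met_minutes(up), ipaq_met_minutes(base))
  }
  p <- scoring_params(daily_cap_minutes = 180)
  p2 <- scoring_params(daily_cap_minutes = 600)
  below <- activity_record(3, 100, 3, 100, 3, 100)
  expect_equal(ipaq_met_minutes(below, p), ipaq_met_minutes(below, p2))
})

test_that("activity score is linear with saturation at the reference volume", {
  expect_equal(score_activity(activity_record()), 0)
  # exactly 3000 MET-min: 5 vigorous days x 75 min = 3000
  expect_equal(score_activity(activity_record(5, 75)), 100)
  expect_equal(score_activity(activity_record(3, 30, 2, 30, 5, 30)), 48.5)
  expect_equal(score_activity(max_activity()), 100)
})

test_that("isolated user with maximal sub-scores: social 0, composite 75", {
  ch <- cohort(list(make_complete_assessment("solo")))
  sc <- compute_scorecards(ch)
  expect_equal(sc$diet_score, 100)
  expect_equal(sc$activity_score, 100)
  expect_equal(sc$bmi_score, 100)
  expect_equal(sc$social_score, 0)
  expect_equal(sc$wakastatus, 75)
  expect_true(sc$converged)
})

test_that("two connected maximal users reach the hand-solved fixed point", {
  ch <- cohort(lapply(c("a", "b"), make_complete_assessment),
               list(relation("a", "b", "friend")))
  sc <- compute_scorecards(ch)
  # closed form: S = 5 + W/2, W = 75 + S/4 => W = 76.25 / 0.875
  expect_equal(sc$wakastatus, rep(76.25 / 0.875, 2), tolerance = 1e-6)
  expect_equal(sc$wakastatus[1], 87.142857, tolerance = 1e-5)
})

test_that("solver agrees with 10,000 naive Jacobi sweeps on a random cohort", {
  ch <- random_small_cohort(25, seed = 42)
  params <- scoring_params()
  sc <- compute_scorecards(ch, params = params)
  oracle <- naive_social_sweeps(sc, ch, params, n_sweeps = 10000)
  expect_equal(sc$wakastatus, oracle$wakastatus, tolerance = 1e-6)
  expect_equal(sc$social_score, oracle$social, tolerance = 1e-6)
})

test_that("fixed point is independent of the initial social vector", {
  ch <- random_small_cohort(20, seed = 7)
  params <- scoring_params()
  sc <- compute_scorecards(ch, params = params)
  # restart from social = 100 via the internal solver
  ids <- sc$user_id
  nbrs <- lapply(seq_along(ids), function(i) integer(0))
  for (r in ch$relations) {
    ia <- match(r$user_a, ids); ib <- match(r$user_b, ids)
    if (!ib %in% nbrs[[ia]]) {
      nbrs[[ia]] <- c(nbrs[[ia]], ib)
      nbrs[[ib]] <- c(nbrs[[ib]], ia)
    }
  }
  alt <- wakamola:::solve_social_fixedpoint(
    sc$diet_score, sc$activity_score, sc$bmi_score, nbrs, lengths(nbrs),
    params, social0 = rep(100, length(ids)))
  expect_equal(alt$wakastatus, sc$wakastatus, tolerance = 1e-6)
})

test_that("all five scores stay in [0, 100] for fuzzed cohorts and parameters", {
  for (seed in 1:5) {
    ch <- random_small_cohort(15, seed = seed)
    params <- withr::with_seed(seed, {
      w <- runif(4); w <- w / sum(w)
      scoring_params(social_degree_weight = runif(1),
                     social_degree_ref = sample(3:15, 1),
                     wakastatus_weights = stats::setNames(
                       w, c("diet", "activity", "bmi", "social")))
    })
    sc <- compute_scorecards(ch, params = params)
    for (col in c("diet_score", "activity_score", "bmi_score",
                  "social_score", "wakastatus")) {
      expect_true(all(sc[[col]] >= -1e-9 & sc[[col]] <= 100 + 1e-9),
                  info = paste(col, "seed", seed))
    }
  }
})

test_that("linking to a maximal-status user never lowers one's social score", {
  mk <- function(rels) {
    ch <- cohort(c(lapply(c("a", "b", "c"), make_complete_assessment),
                   list(make_complete_assessment("weak", weight = 120,
                                                 height = 1.6,
                                                 diet = worst_diet_answers(),
                                                 activity = activity_record()))),
                 rels)
    compute_scorecards(ch)
  }
  before <- mk(list(relation("weak", "a", "friend")))
  after <- mk(list(relation("weak", "a", "friend"),
                   relation("weak", "b", "friend")))
  sw_before <- before$social_score[before$user_id == "weak"]
  sw_after <- after$social_score[after$user_id == "weak"]
  expect_gte(sw_after, sw_before)
})

test_that("incomplete participants are excluded and reported", {
  full <- make_complete_assessment("x")
  part <- assessment("y", personal = full$personal)
  sc <- compute_scorecards(cohort(list(full, part)))
  expect_equal(sc$user_id, "x")
  expect_equal(attr(sc, "excluded"), "y")
})

test_that("wakastatus equals the weighted sum of the four sub-scores", {
  ch <- random_small_cohort(12, seed = 3)
  sc <- compute_scorecards(ch)
  recomputed <- 0.25 * (sc$diet_score + sc$activity_score + sc$bmi_score +
                          sc$social_score)
  expect_equal(sc$wakastatus, recomputed, tolerance = 1e-6)
})
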