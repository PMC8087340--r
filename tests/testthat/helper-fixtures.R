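# Fixtures are built in code; no stored data.

# Diet answer sheets hitting the normalization endpoints: per item class the
# level with minimal / maximal penalty under the shipped default_v1 table
# (daily: L5 / L0, weekly: L3 / L0, occasional: L0 / L5).
best_diet_answers <- function() {
  items <- canonical_food_items()
  lev <- c(daily = "L5", weekly = "L3", occasional = "L0")[items$item_class]
  stats::setNames(lev, items$item_id)
}

worst_diet_answers <- function() {
  items <- canonical_food_items()
  lev <- c(daily = "L0", weekly = "L0", occasional = "L5")[items$item_class]
  stats::setNames(lev, items$item_id)
}

# Saturating activity: well above 3000 MET-min/week after capping.
max_activity <- function() activity_record(7, 180, 7, 180, 7, 180, 10)

make_complete_assessment <- function(id, weight = 65, height = 1.75,
                                     diet = best_diet_answers(),
                                     activity = max_activity()) {
  assessment(id,
             personal = personal_record(weight, height, gender = "female",
                                        age = 21, sleep_hours = 8),
             diet = diet_record(diet),
             activity = activity)
}

# 3-item toy score table (single 'occasional' class, penalties 1..10 by
# level) with P_min = 3, P_max = 30.
toy_score_table <- function() {
  items <- data.frame(item_id = c("a", "b", "c"), group = "toy",
                      item_class = "occasional",
                      label = c("A", "B", "C"), stringsAsFactors = FALSE)
  score_table(config = list(
    name = "toy",
    penalties = list(occasional = c(1, 2, 4, 6, 8, 10)),
    level_upper_bounds = list(0, 1, 3, 7, 14, NULL),
    level_representative_units = c(0, 0.5, 2, 4.5, 9, 16)
  ), items = items)
}

# Cohort whose relation graph is two 5-cliques bridged by one edge
# (nodes c01..c05 and d01..d05; bridge c01-d01).
two_clique_cohort <- function() {
  ids <- c(sprintf("c%02d", 1:5), sprintf("d%02d", 1:5))
  rels <- list()
  for (grp in list(ids[1:5], ids[6:10]))
    for (i in 1:4) for (j in (i + 1):5)
      rels[[length(rels) + 1]] <- relation(grp[i], grp[j], "friend")
  rels[[length(rels) + 1]] <- relation("c01", "d01", "work")
  cohort(lapply(ids, make_complete_assessment), rels)
}

# --- independent oracles ----------------------------------------------------

# All set partitions of n elements as membership vectors, enumerated by
# restricted growth strings.
all_partitions <- function(n) {
  out <- list()
  rec <- function(prefix, maxk) {
    i <- length(prefix) + 1L
    if (i > n) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible())
    }
    for (k in seq_len(maxk + 1L)) rec(c(prefix, k), max(maxk, k))
  }
  rec(integer(0), 0L)
  out
}

# Exhaustive modularity maximisation over every partition of the graph's
# nodes (feasible for <= 10 nodes).
brute_force_best_partition <- function(g) {
  parts <- all_partitions(igraph::vcount(g))
  mods <- vapply(parts, function(m) igraph::modularity(g, m), numeric(1))
  list(membership = parts[[which.max(mods)]], modularity = max(mods))
}

# Naive Jacobi sweeps for the social/composite fixed point, written
# independently of the package solver: plain loops, fixed sweep count.
naive_social_sweeps <- function(scorecards, cohort, params, n_sweeps = 10000,
                                social0 = rep(0, nrow(scorecards))) {
  ids <- scorecards$user_id
  n <- length(ids)
  w <- params$wakastatus_weights
  adj <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  for (r in cohort$relations)
    if (r$user_a %in% ids && r$user_b %in% ids) {
      adj[r$user_a, r$user_b] <- TRUE
      adj[r$user_b, r$user_a] <- TRUE
    }
  social <- social0
  waka <- numeric(n)
  for (s in seq_len(n_sweeps)) {
    waka <- w[["diet"]] * scorecards$diet_score +
      w[["activity"]] * scorecards$activity_score +
      w[["bmi"]] * scorecards$bmi_score + w[["social"]] * social
    new_social <- numeric(n)
    for (i in seq_len(n)) {
      nb <- which(adj[i, ])
      d <- length(nb)
      q <- if (d == 0) 0 else mean(waka[nb]) / 100
      new_social[i] <- 100 * (params$social_degree_weight *
                                min(d / params$social_degree_ref, 1) +
                              (1 - params$social_degree_weight) * q)
    }
    social <- new_social
  }
  waka <- w[["diet"]] * scorecards$diet_score +
    w[["activity"]] * scorecards$activity_score +
    w[["bmi"]] * scorecards$bmi_score + w[["social"]] * social
  list(social = social, wakastatus = waka)
}

# Random valid cohort for fuzz tests: random scores territory, random sparse
# relations.
random_small_cohort <- function(n, seed) {
  withr::with_seed(seed, {
    items <- canonical_food_items()
    ids <- sprintf("r%03d", seq_len(n))
    assessments <- lapply(ids, function(id) {
      lev <- sample(c("L0", "L1", "L2", "L3", "L4", "L5"),
                    nrow(items), replace = TRUE)
      assessment(id,
                 personal = personal_record(runif(1, 45, 150), runif(1, 1.4, 2.1),
                                            age = runif(1, 16, 80),
                                            sleep_hours = runif(1, 4, 11)),
                 diet = diet_record(stats::setNames(lev, items$item_id)),
                 activity = activity_record(sample(0:7, 1), runif(1, 0, 400),
                                            sample(0:7, 1), runif(1, 0, 400),
                                            sample(0:7, 1), runif(1, 0, 400),
                                            runif(1, 0, 80)))
    })
    pairs <- t(utils::combn(ids, 2))
    keep <- runif(nrow(pairs)) < 0.15
    rels <- lapply(which(keep), function(k)
      relation(pairs[k, 1], pairs[k, 2],
               sample(c("home", "family", "friend", "work"), 1)))
    cohort(assessments, rels)
  })
}
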