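test_that("graph construction keeps isolated nodes and merges typed duplicates", {
  as3 <- lapply(c("a", "b", "c"), make_complete_assessment)
  ch <- cohort(as3, list(relation("a", "b", "friend"),
                         relation("a", "b", "work")))
  sc <- compute_scorecards(ch)
  g <- build_graph(ch, sc)
  expect_equal(igraph::vcount(g), 3)
  expect_equal(igraph::ecount(g), 1)       # duplicate pair merged
  expect_equal(igraph::E(g)$rel_types, "friend,work")
  expect_equal(sum(igraph::degree(g) == 0), 1)

  empty <- cohort(as3, list())
  g0 <- build_graph(empty, compute_scorecards(empty))
  expect_equal(igraph::ecount(g0), 0)
  expect_equal(sum(igraph::degree(g0) == 0), 3)
})

test_that("graph construction rejects dangling relation endpoints", {
  ch <- cohort(lapply(c("a", "b"), make_complete_assessment),
               list(relation("a", "b", "friend")))
  sc <- compute_scorecards(ch)
  sc1 <- sc[sc$user_id == "a", ]
  expect_error(build_graph(ch, sc1), "b")
})

test_that("Louvain on the two-clique fixture matches exhaustive modularity maximisation", {
  ch <- two_clique_cohort()
  sc <- compute_scorecards(ch)
  g <- build_graph(ch, sc)
  part <- detect_communities(g, seed = 0)
  # brute force over all 115,975 partitions of the 10 nodes
  best <- brute_force_best_partition(g)
  expect_equal(igraph::modularity(g, part[igraph::V(g)$name] + 1),
               best$modularity, tolerance = 1e-12)
  # the optimum splits the two cliques
  cl1 <- part[sprintf("c%02d", 1:5)]
  cl2 <- part[sprintf("d%02d", 1:5)]
  expect_equal(length(unique(cl1)), 1)
  expect_equal(length(unique(cl2)), 1)
  expect_false(cl1[1] == cl2[1])
})

test_that("community detection is deterministic and gives singletons on edgeless graphs", {
  ch <- two_clique_cohort()
  sc <- compute_scorecards(ch)
  g <- build_graph(ch, sc)
  expect_identical(detect_communities(g, seed = 0),
                   detect_communities(g, seed = 0))

  as5 <- lapply(sprintf("i%d", 1:5), make_complete_assessment)
  ch0 <- cohort(as5)
  g0 <- build_graph(ch0, compute_scorecards(ch0))
  p0 <- detect_communities(g0, seed = 0)
  expect_equal(sort(unique(p0)), 0:4)
})

test_that("network summary counts nodes, edges, isolates and community composition", {
  as5 <- lapply(sprintf("i%d", 1:5), make_complete_assessment)
  ch0 <- cohort(as5)
  g0 <- build_graph(ch0, compute_scorecards(ch0))
  s0 <- network_summary(g0, detect_communities(g0, seed = 0))
  expect_equal(s0$n_isolated, 5)
  expect_equal(s0$n_communities, 5)
  expect_equal(s0$n_communities_multi, 0)

  tri_ids <- c("t1", "t2", "t3")
  ch3 <- cohort(lapply(tri_ids, make_complete_assessment),
                list(relation("t1", "t2", "friend"),
                     relation("t2", "t3", "friend"),
                     relation("t1", "t3", "friend")))
  g3 <- build_graph(ch3, compute_scorecards(ch3))
  s3 <- network_summary(g3, detect_communities(g3, seed = 0))
  expect_equal(s3$n_communities, 1)
  expect_equal(s3$largest_community_size, 3)
  expect_equal(s3$n_isolated, 0)
})

test_that("community composition reports the printed percentage style", {
  # 12-member community, 3 overweight -> 25%
  ids <- sprintf("m%02d", 1:12)
  mk <- function(id, ow) make_complete_assessment(
    id, weight = if (ow) 80 else 65, height = 1.70)
  as12 <- mapply(mk, ids, c(rep(TRUE, 3), rep(FALSE, 9)), SIMPLIFY = FALSE)
  rels <- list()
  for (i in 2:12) rels[[i - 1]] <- relation(ids[1], ids[i], "friend")
  ch <- cohort(as12, rels)
  sc <- compute_scorecards(ch)
  g <- build_graph(ch, sc)
  s <- network_summary(g, detect_communities(g, seed = 0))
  comp <- s$community_composition
  ow <- comp[comp$bmi_category == "overweight" & comp$size == 12, ]
  expect_equal(ow$count, 3)
  expect_equal(ow$pct, 25)
})

test_that("BMI colours follow the figure legend and agree with categories", {
  expect_equal(color_for_bmi(17), "blue")
  expect_equal(color_for_bmi(27), "yellow")
  expect_equal(color_for_bmi(31), "red")
  expect_equal(color_for_bmi(21.4), "green")
  grid <- seq(12, 55, by = 0.5)
  map <- c(underweight = "blue", normal = "green", overweight = "yellow",
           obesity1 = "red", obesity2 = "red", obesity3 = "red")
  expect_equal(color_for_bmi(grid),
               unname(map[as.character(bmi_category(grid))]))
})

test_that("ego tables list neighbours sorted by status and match the scorecards", {
  ch <- cohort(c(lapply(c("a", "b", "c"), make_complete_assessment),
                 list(make_complete_assessment("low", weight = 95, height = 1.70,
                                               activity = activity_record())),
                 list(make_complete_assessment("iso"))),
               list(relation("a", "b", "friend"),
                    relation("a", "c", "family"),
                    relation("a", "low", "work")))
  sc <- compute_scorecards(ch)
  g <- build_graph(ch, sc)
  et <- ego_table(g, "a")
  expect_equal(nrow(et), 3)
  expect_true(all(diff(et$wakastatus) <= 0))
  expect_equal(et$neighbor_id[3], "low")      # lowest status last
  for (i in seq_len(nrow(et))) {
    row <- sc[sc$user_id == et$neighbor_id[i], ]
    expect_equal(et$wakastatus[i], row$wakastatus)
    expect_equal(et$bmi[i], row$bmi)
  }
  expect_equal(nrow(ego_table(g, "iso")), 0)
  expect_error(ego_table(g, "nobody"), "unknown user")
})

test_that("graph exports round-trip through GraphML and node-link JSON", {
  ch <- two_clique_cohort()
  sc <- compute_scorecards(ch)
  g <- build_graph(ch, sc)
  part <- detect_communities(g, seed = 0)

  for (fmt in c("graphml", "json")) {
    path <- withr::local_tempfile(fileext = paste0(".", fmt))
    export_graph(g, part, path, fmt)
    g2 <- import_graph(path, fmt)
    expect_equal(igraph::vcount(g2), igraph::vcount(g))
    expect_equal(igraph::ecount(g2), igraph::ecount(g))
    ord <- match(igraph::V(g)$name, igraph::V(g2)$name)
    expect_equal(igraph::V(g2)$bmi[ord], igraph::V(g)$bmi)
    expect_equal(igraph::V(g2)$wakastatus[ord], igraph::V(g)$wakastatus)
    expect_equal(igraph::V(g2)$color[ord], igraph::V(g)$color)
    expect_equal(as.integer(igraph::V(g2)$community[ord]),
                 as.integer(part[igraph::V(g)$name]))
    # same edge set by endpoint names
    el <- function(gr) {
      e <- igraph::as_edgelist(gr)
      sort(paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2])))
    }
    expect_equal(el(g2), el(g))
    expect_true(igraph::isomorphic(g, g2))
  }
})

test_that("exporting an empty graph yields a valid, re-importable file", {
  ch0 <- cohort(list())
  g0 <- build_graph(ch0, compute_scorecards(ch0))
  path <- withr::local_tempfile(fileext = ".json")
  export_graph(g0, stats::setNames(integer(0), character(0)), path, "json")
  g2 <- import_graph(path, "json")
  expect_equal(igraph::vcount(g2), 0)
})

test_that("partition sizes sum to node count; isolates are degree-0 nodes", {
  for (seed in 1:3) {
    ch <- random_small_cohort(12, seed = seed)
    sc <- compute_scorecards(ch)
    g <- build_graph(ch, sc)
    part <- detect_communities(g, seed = 0)
    s <- network_summary(g, part)
    expect_equal(sum(table(part)), s$n_nodes)
    expect_equal(s$n_isolated, sum(igraph::degree(g) == 0))
  }
})
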