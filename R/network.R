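# Typed relation graph and community structure. The graph is simple and
# undirected: duplicate typed relations between the same pair collapse into
# one edge carrying the set of relation types (attribute rel_types, a
# comma-joined string in canonical order).

#' Build the relation graph for a scored cohort
#'
#' Nodes are the scored participants (isolated nodes retained) with score
#' attributes attached; edges are unordered participant pairs with a set of
#' relation types.
#'
#' @param cohort \code{cohort}.
#' @param scorecards data frame from \code{\link{compute_scorecards}}.
#' @return \code{igraph} object with node attributes bmi, bmi_cat,
#'   wakastatus, color and edge attribute rel_types.
#' @export
build_graph <- function(cohort, scorecards) {
  ids <- scorecards$user_id
  for (r in cohort$relations) {
    if (!(r$user_a %in% ids) || !(r$user_b %in% ids))
      stop("relation (", r$user_a, ", ", r$user_b, ", ", r$relation_type,
           ") references an unscored participant", call. = FALSE)
  }
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(ids), name = ids,
                            bmi = scorecards$bmi,
                            bmi_cat = scorecards$bmi_category,
                            wakastatus = scorecards$wakastatus,
                            color = color_for_bmi(scorecards$bmi))
  if (length(cohort$relations)) {
    pair_key <- vapply(cohort$relations, function(r)
      paste(r$user_a, r$user_b, sep = "\r"), character(1))
    types <- split(vapply(cohort$relations, `[[`, character(1), "relation_type"),
                   pair_key)
    pairs <- do.call(rbind, strsplit(names(types), "\r", fixed = TRUE))
    rel_types <- vapply(types, function(tt)
      paste(RELATION_TYPES[RELATION_TYPES %in% tt], collapse = ","),
      character(1))
    g <- igraph::add_edges(g, rbind(pairs[, 1], pairs[, 2]),
                           rel_types = unname(rel_types))
  }
  g
}

#' Detect communities with the Louvain algorithm
#'
#' Runs Louvain modularity optimisation at the given resolution. Isolated
#' nodes each form their own singleton community. The partition is made
#' deterministic by seeding R's RNG and processing vertices in sorted-id
#' order; community ids are relabelled contiguously from 0 in order of first
#' appearance over sorted node ids.
#'
#' @param graph \code{igraph} from \code{\link{build_graph}}.
#' @param seed integer RNG seed (default 0).
#' @param resolution Louvain resolution parameter (default 1).
#' @return Named integer vector: community id (0-based) per node.
#' @export
detect_communities <- function(graph, seed = 0, resolution = 1) {
  ord <- order(igraph::V(graph)$name)
  g <- igraph::permute(graph, match(seq_along(ord), ord))
  memb <- withr::with_seed(seed, {
    if (igraph::ecount(g) == 0) seq_len(igraph::vcount(g))
    else igraph::membership(igraph::cluster_louvain(g, resolution = resolution))
  })
  ids <- igraph::V(g)$name
  relabel <- match(memb, unique(memb)) - 1L
  out <- setNames(as.integer(relabel), ids)
  out[igraph::V(graph)$name]
}

#' Summarise a partitioned relation graph
#'
#' @param graph \code{igraph}.
#' @param partition named community vector from
#'   \code{\link{detect_communities}}.
#' @return List: n_nodes, n_edges, n_isolated, n_communities,
#'   n_communities_multi, largest_community_size, and
#'   \code{community_composition}, a data frame of per-community counts of
#'   each BMI category with percentages (one decimal, half-up).
#' @export
network_summary <- function(graph, partition) {
  stopifnot(setequal(names(partition), igraph::V(graph)$name))
  partition <- partition[igraph::V(graph)$name]
  sizes <- table(partition)
  cats <- igraph::V(graph)$bmi_cat
  comp <- do.call(rbind, lapply(names(sizes), function(cm) {
    in_cm <- partition == as.integer(cm)
    n <- sum(in_cm)
    counts <- table(factor(cats[in_cm],
                           levels = c("underweight", "normal", "overweight",
                                      "obesity1", "obesity2", "obesity3")))
    data.frame(community = as.integer(cm), size = n,
               bmi_category = names(counts), count = as.integer(counts),
               pct = round_half_up(100 * as.integer(counts) / n, 1),
               stringsAsFactors = FALSE)
  }))
  list(
    n_nodes = igraph::vcount(graph),
    n_edges = igraph::ecount(graph),
    n_isolated = sum(igraph::degree(graph) == 0),
    n_communities = length(sizes),
    n_communities_multi = sum(sizes > 1),
    largest_community_size = if (length(sizes)) max(sizes) else 0L,
    community_composition = comp
  )
}

# round-half-up (base round() is banker's rounding); matches the printed
# percentage style 6.8% = 5/74, 10.8% = 8/74.
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Node colour for the network view
#'
#' Figure-style BMI colour coding: blue (underweight, < 18.5), green (normal,
#' [18.5, 25)), yellow (overweight, [25, 30)), red (obesity, >= 30).
#'
#' @param bmi BMI in kg/m^2 (vectorised).
#' @return Character vector of colour names.
#' @export
color_for_bmi <- function(bmi) {
  cat <- as.character(bmi_category(bmi))
  unname(c(underweight = "blue", normal = "green", overweight = "yellow",
           obesity1 = "red", obesity2 = "red", obesity3 = "red")[cat])
}

#' Ego table: a participant's neighbours and their scores
#'
#' One row per neighbour with relation types, BMI, BMI category and
#' Wakastatus, sorted by Wakastatus descending (ties broken by id).
#'
#' @param graph \code{igraph} from \code{\link{build_graph}}.
#' @param user_id participant id present in the graph.
#' @return Data frame: neighbor_id, rel_types, bmi, bmi_category, wakastatus.
#' @export
ego_table <- function(graph, user_id) {
  names <- igraph::V(graph)$name
  if (!user_id %in% names)
    stop("unknown user '", user_id, "'", call. = FALSE)
  v <- which(names == user_id)
  inc <- igraph::incident(graph, v)
  nb <- igraph::neighbors(graph, v)
  out <- data.frame(
    neighbor_id = names[as.integer(nb)],
    rel_types = if (length(inc)) igraph::edge_attr(graph, "rel_types", inc) else character(0),
    bmi = igraph::V(graph)$bmi[as.integer(nb)],
    bmi_category = igraph::V(graph)$bmi_cat[as.integer(nb)],
    wakastatus = igraph::V(graph)$wakastatus[as.integer(nb)],
    stringsAsFactors = FALSE
  )
  out <- out[order(-out$wakastatus, out$neighbor_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Export the relation graph
#'
#' Writes GraphML (via igraph) or node-link JSON with node attributes bmi,
#' bmi_cat, wakastatus, color, community and edge attribute rel_types.
#' Re-importing with \code{\link{import_graph}} reproduces the graph.
#'
#' @param graph \code{igraph}.
#' @param partition community vector (attached as node attribute).
#' @param path output file.
#' @param format "graphml" or "json".
#' @return \code{path}, invisibly.
#' @export
export_graph <- function(graph, partition, path,
                         format = c("graphml", "json")) {
  format <- match.arg(format)
  igraph::V(graph)$community <- as.integer(partition[igraph::V(graph)$name])
  if (format == "graphml") {
    igraph::write_graph(graph, path, format = "graphml")
  } else {
    nodes <- lapply(seq_len(igraph::vcount(graph)), function(i) list(
      id = igraph::V(graph)$name[i], bmi = igraph::V(graph)$bmi[i],
      bmi_cat = igraph::V(graph)$bmi_cat[i],
      wakastatus = igraph::V(graph)$wakastatus[i],
      color = igraph::V(graph)$color[i],
      community = igraph::V(graph)$community[i]))
    el <- igraph::as_edgelist(graph)
    links <- lapply(seq_len(nrow(el)), function(i) list(
      source = el[i, 1], target = el[i, 2],
      rel_types = igraph::E(graph)$rel_types[i]))
    jsonlite::write_json(list(directed = FALSE, nodes = nodes, links = links),
                         path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Import a graph written by \code{\link{export_graph}}
#'
#' @param path file to read.
#' @param format "graphml" or "json".
#' @return \code{igraph} with the exported attributes.
#' @export
import_graph <- function(path, format = c("graphml", "json")) {
  format <- match.arg(format)
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    # igraph stores 'name' under id on write; normalise back
    if (!"name" %in% igraph::vertex_attr_names(g) &&
        "id" %in% igraph::vertex_attr_names(g))
      igraph::V(g)$name <- igraph::V(g)$id
    return(g)
  }
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  getv <- function(field) vapply(obj$nodes, function(n) n[[field]], character(1))
  g <- igraph::add_vertices(g, length(obj$nodes),
                            name = getv("id"),
                            bmi = vapply(obj$nodes, function(n) as.numeric(n$bmi), numeric(1)),
                            bmi_cat = getv("bmi_cat"),
                            wakastatus = vapply(obj$nodes, function(n) as.numeric(n$wakastatus), numeric(1)),
                            color = getv("color"),
                            community = vapply(obj$nodes, function(n) as.integer(n$community), integer(1)))
  if (length(obj$links)) {
    ends <- unlist(lapply(obj$links, function(l) c(l$source, l$target)))
    g <- igraph::add_edges(g, ends,
                           rel_types = vapply(obj$links, function(l) l$rel_types, character(1)))
  }
  g
}
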