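#' Disease-exclusive differential subnetworks
#'
#' Compares two co-consumption networks over the same node universe and
#' splits their edge union into three parts: edges exclusive to network A,
#' edges exclusive to network B, and shared edges. Edge identity is the
#' unordered food pair (weights are ignored for membership). Each exclusive
#' edge set induces a subnetwork whose nodes are exactly the foods touching
#' at least one exclusive edge, carrying the weights of its source network.
#'
#' @param net_a,net_b `ccn` objects with identical node universes.
#' @return A `dccn_diff` object: list with `exclusive_a` and `exclusive_b`
#'   (edge-induced `ccn` subnetworks) and `shared_edges` (tibble with both
#'   networks' weights).
#' @export
differential <- function(net_a, net_b) {
  stopifnot(inherits(net_a, "ccn"), inherits(net_b, "ccn"))
  diff_nodes <- c(setdiff(net_a$nodes, net_b$nodes),
                  setdiff(net_b$nodes, net_a$nodes))
  if (length(diff_nodes)) {
    stop_dccn(paste0("Node universes differ: ",
                     paste(sort(unique(diff_nodes)), collapse = ", ")),
              "dccn_input_error")
  }
  key_a <- edge_key(net_a$edges$food_a, net_a$edges$food_b)
  key_b <- edge_key(net_b$edges$food_a, net_b$edges$food_b)

  excl_a <- net_a$edges[!key_a %in% key_b, ]
  excl_b <- net_b$edges[!key_b %in% key_a, ]
  shared_a <- net_a$edges[key_a %in% key_b, ]
  shared_b <- net_b$edges[key_b %in% key_a, ]
  shared <- dplyr::inner_join(
    dplyr::rename(shared_a, weight_a = "weight"),
    dplyr::select(
      dplyr::rename(shared_b, weight_b = "weight"),
      "food_a", "food_b", "weight_b"
    ),
    by = c("food_a", "food_b")
  )

  induced <- function(edges, group) {
    new_ccn(edges,
            nodes = sort(unique(c(edges$food_a, edges$food_b))),
            group = group)
  }
  structure(
    list(
      exclusive_a = induced(excl_a, paste0(net_a$group, "_exclusive")),
      exclusive_b = induced(excl_b, paste0(net_b$group, "_exclusive")),
      shared_edges = shared
    ),
    class = "dccn_diff"
  )
}

#' @export
print.dccn_diff <- function(x, ...) {
  cat("<differential co-consumption networks>\n")
  cat(sprintf("  %s: %d nodes, %d edges\n", x$exclusive_a$group,
              length(x$exclusive_a$nodes), nrow(x$exclusive_a$edges)))
  cat(sprintf("  %s: %d nodes, %d edges\n", x$exclusive_b$group,
              length(x$exclusive_b$nodes), nrow(x$exclusive_b$edges)))
  cat(sprintf("  shared: %d edges\n", nrow(x$shared_edges)))
  invisible(x)
}

#' Tidy differential networks into one edge table
#' @param x A `dccn_diff` object.
#' @param ... Unused.
#' @return Tibble of all edges with a `membership` column
#'   (`exclusive_a`, `exclusive_b`, `shared`).
#' @method tidy dccn_diff
#' @export
tidy.dccn_diff <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$exclusive_a$edges, membership = "exclusive_a"),
    dplyr::mutate(x$exclusive_b$edges, membership = "exclusive_b"),
    dplyr::mutate(
      dplyr::select(x$shared_edges, "food_a", "food_b", weight = "weight_a"),
      membership = "shared"
    )
  )
}

#' Two-step ego network of a focal food
#'
#' Induced subgraph on all foods within `steps` hops (unweighted path
#' distance) of the focal food, focal included. Used to show the local
#' co-consumption neighborhood of a hub food.
#'
#' @param net A `ccn` object.
#' @param focal Focal food name (must be a node of `net`).
#' @param steps Hop radius (default 2).
#' @return A `ccn` object restricted to the ego neighborhood.
#' @export
ego_network <- function(net, focal, steps = 2) {
  stopifnot(inherits(net, "ccn"))
  if (!focal %in% net$nodes) {
    stop_dccn(sprintf("Focal food '%s' is not a node of the network.", focal),
              "dccn_input_error")
  }
  g <- as_igraph(net)
  ego_v <- igraph::ego(g, order = steps, nodes = focal)[[1]]
  members <- names(ego_v)
  if (igraph::degree(g, focal) == 0) {
    warn(sprintf("Focal food '%s' is an isolate; ego network is a single node.",
                 focal))
  }
  edges <- net$edges[net$edges$food_a %in% members &
                       net$edges$food_b %in% members, ]
  new_ccn(edges, nodes = members,
          group = paste0(net$group, ":ego:", focal),
          params = list(focal = focal, steps = steps))
}

#' Graph summary statistics
#'
#' Number of nodes and edges, average degree `2E/N`, density
#' `2E/(N(N-1))`, and the global clustering coefficient (transitivity,
#' `3 x triangles / connected triples`). A single-node graph reports density
#' and clustering 0 with `degenerate = TRUE`.
#'
#' @param net A `ccn` object (or anything [as_igraph()] accepts).
#' @return One-row tibble: `n_nodes`, `n_edges`, `average_degree`, `density`,
#'   `clustering`, `degenerate`.
#' @export
graph_summary <- function(net) {
  g <- as_igraph(net)
  n <- igraph::vcount(g)
  e <- igraph::ecount(g)
  if (n == 0) stop_dccn("Empty graph.", "dccn_input_error")
  if (n == 1) {
    return(tibble::tibble(n_nodes = 1L, n_edges = 0L, average_degree = 0,
                          density = 0, clustering = 0, degenerate = TRUE))
  }
  cl <- igraph::transitivity(g, type = "global")
  tibble::tibble(
    n_nodes = n,
    n_edges = e,
    average_degree = 2 * e / n,
    density = 2 * e / (n * (n - 1)),
    clustering = ifelse(is.nan(cl), 0, cl),
    degenerate = FALSE
  )
}

#' Summaries of ego networks around a set of focal foods
#'
#' @param net A `ccn` object.
#' @param focal Character vector of focal foods.
#' @param steps Hop radius (default 2).
#' @return List with `per_ego` (one row per focal food) and `mean` (one-row
#'   tibble of arithmetic means over the focal foods).
#' @export
summarize_egos <- function(net, focal, steps = 2) {
  per_ego <- purrr::map_dfr(focal, function(f) {
    dplyr::bind_cols(tibble::tibble(focal = f),
                     graph_summary(ego_network(net, f, steps = steps)))
  })
  means <- dplyr::summarise(
    per_ego,
    dplyr::across(c("n_nodes", "n_edges", "average_degree",
                    "density", "clustering"), mean)
  )
  list(per_ego = per_ego, mean = means)
}
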