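#' Five node centralities, z-standardized and integrated
#'
#' Computes, for every node of a (sub)network, the five centrality measures
#' used to weight foods in the D_CCN score, z-standardizes each across the
#' nodes of the scored graph, and averages the five z-scores into a single
#' integrated centrality per node:
#' \describe{
#'   \item{degree}{number of incident edges (connections);}
#'   \item{strength}{sum of absolute edge weights (interaction strength);}
#'   \item{betweenness}{shortest-path betweenness with distance `1/|w|`,
#'     normalized by `(N-1)(N-2)/2` (mediation);}
#'   \item{closeness}{per connected component, reachable nodes divided by
#'     the sum of `1/|w|` distances to them; 0 for isolates (position);}
#'   \item{eigenvector}{power iteration on the `|w|` adjacency of the
#'     largest connected component, scaled to maximum 1; nodes outside that
#'     component get 0 (influence).}
#' }
#' Negative edge weights occur (staple-substitution edges); all distance and
#' strength computations use `|w|`, while the sign stays on the edges.
#' Zero-variance centrality columns get z-score 0 so the integrated value is
#' always a mean over exactly five components. Ties in the integrated
#' ranking break lexicographically by food name.
#'
#' @param net A `ccn` object (signed weighted edges; unweighted graphs are
#'   treated as unit weights).
#' @param max_iter,tol Power-iteration cap and convergence tolerance for the
#'   eigenvector measure.
#' @return A tibble with one row per node: `food`, the five raw measures,
#'   their `z_*` columns, `integrated_centrality`, and `rank`
#'   (1 = highest integrated centrality).
#' @export
centralities <- function(net, max_iter = 1000L, tol = 1e-12) {
  g <- as_igraph(net)
  n <- igraph::vcount(g)
  if (n == 0) stop_dccn("Empty graph.", "dccn_input_error")
  w <- igraph::E(g)$weight
  if (is.null(w)) w <- rep(1, igraph::ecount(g))
  aw <- abs(w)
  dist_w <- 1 / aw

  degree <- igraph::degree(g)
  strength <- igraph::strength(g, weights = aw)
  betweenness <- if (n > 2) {
    igraph::betweenness(g, weights = dist_w, normalized = TRUE)
  } else {
    setNames(rep(0, n), igraph::V(g)$name)
  }
  d <- igraph::distances(g, weights = dist_w)
  closeness <- apply(d, 1, function(row) {
    reach <- is.finite(row) & row > 0
    if (!any(reach)) 0 else sum(reach) / sum(row[reach])
  })
  eigenvector <- eigenvector_largest_component(g, aw, max_iter, tol)

  raw <- tibble::tibble(
    food = igraph::V(g)$name,
    degree = as.integer(degree),
    strength = unname(strength),
    betweenness = unname(betweenness),
    closeness = unname(closeness),
    eigenvector = unname(eigenvector)
  )
  zcol <- function(x) {
    s <- sd(x)
    if (is.na(s) || s == 0) rep(0, length(x)) else (x - mean(x)) / s
  }
  out <- dplyr::mutate(
    raw,
    z_degree = zcol(.data$degree),
    z_strength = zcol(.data$strength),
    z_betweenness = zcol(.data$betweenness),
    z_closeness = zcol(.data$closeness),
    z_eigenvector = zcol(.data$eigenvector),
    integrated_centrality = (.data$z_degree + .data$z_strength +
      .data$z_betweenness + .data$z_closeness + .data$z_eigenvector) / 5
  )
  ord <- order(-out$integrated_centrality, out$food)
  out$rank <- integer(nrow(out))
  out$rank[ord] <- seq_len(nrow(out))
  dplyr::arrange(out, .data$rank)
}

# Leading eigenvector of the |w| adjacency of the largest connected
# component (ties: the component containing the alphabetically first node
# among the largest), by power iteration, scaled so max = 1.
eigenvector_largest_component <- function(g, aw, max_iter, tol) {
  comp <- igraph::components(g)
  out <- setNames(rep(0, igraph::vcount(g)), igraph::V(g)$name)
  big <- which(comp$csize == max(comp$csize))[1]
  members <- which(comp$membership == big)
  if (length(members) == 1) {
    out[members] <- 1
    return(out)
  }
  sub <- igraph::induced_subgraph(g, members)
  adj <- igraph::as_adjacency_matrix(
    sub, attr = "weight", sparse = FALSE
  )
  adj <- abs(adj)
  # spectral shift: A + cI has the same eigenvectors but breaks the +/- pair
  # of bipartite graphs (e.g. stars), so power iteration always converges
  shift <- max(rowSums(adj))
  adj_s <- adj + diag(shift, nrow(adj))
  v <- rep(1 / sqrt(nrow(adj)), nrow(adj))
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    nv <- adj_s %*% v
    nv <- nv / sqrt(sum(nv^2))
    if (max(abs(nv - v)) < tol) {
      v <- nv
      converged <- TRUE
      break
    }
    v <- as.numeric(nv)
  }
  if (!converged) {
    stop_dccn(
      sprintf("Power iteration did not converge in %d iterations.", max_iter),
      "dccn_convergence_error"
    )
  }
  v <- abs(as.numeric(v))
  out[rownames(adj)] <- v / max(v)
  out
}

#' Hierarchical network-role classification
#'
#' Assigns each food exactly one role by the first matching rule:
#' \enumerate{
#'   \item rank 1 and eigenvector centrality >= 0.8: `primary_hub`;
#'   \item rank 2-3: `hub_food`;
#'   \item betweenness centrality >= 0.15: `bridge`;
#'   \item degree >= 2: `connector`;
#'   \item otherwise (`degree < 2`): `peripheral`.
#' }
#'
#' @param table A centrality table with columns `food`, `rank`,
#'   `eigenvector`, `betweenness`, `degree` (e.g. from [centralities()]).
#' @return The input tibble with a `role` factor column appended.
#' @export
classify_roles <- function(table) {
  table <- tibble::as_tibble(table)
  need <- c("food", "rank", "eigenvector", "betweenness", "degree")
  missing <- setdiff(need, names(table))
  if (length(missing)) {
    stop_dccn(paste0("Centrality table is missing column(s): ",
                     paste(missing, collapse = ", ")),
              "dccn_input_error")
  }
  lvls <- c("primary_hub", "hub_food", "bridge", "connector", "peripheral")
  role <- dplyr::case_when(
    table$rank == 1 & table$eigenvector >= 0.8 ~ "primary_hub",
    table$rank %in% c(2, 3) ~ "hub_food",
    table$betweenness >= 0.15 ~ "bridge",
    table$degree >= 2 ~ "connector",
    TRUE ~ "peripheral"
  )
  dplyr::mutate(table, role = factor(role, levels = lvls))
}
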