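#' Build a co-consumption network by stability selection
#'
#' Constructs an undirected food co-consumption network for one outcome
#' group. On each of `n_iter` random subsamples (default: half the group,
#' drawn without replacement) the full matrix of sex- and energy-adjusted
#' partial Spearman correlations among the food columns is computed. An edge
#' between two foods is retained only if
#' \itemize{
#'   \item the mean signed correlation across iterations exceeds
#'     `r_threshold` in absolute value, and
#'   \item the correlation is significant (`p < alpha`) in every iteration.
#' }
#' The retained edge weight is the mean signed correlation. Foods whose
#' intake is constant within a subsample are kept as isolated nodes with a
#' warning.
#'
#' @param intake Data frame or matrix of cumulative-average intakes
#'   (participants x foods, servings/day), restricted to one outcome group.
#'   A column named `id` is ignored if present.
#' @param covariates Data frame or matrix of adjustment covariates (same
#'   rows), typically energy (kcal/day) and sex (female = 1, male = 0).
#' @param n_iter Number of subsample iterations (default 100).
#' @param subsample_frac Fraction subsampled per iteration (default 0.5).
#' @param r_threshold Retention threshold on `|mean r|` (default 0.2).
#' @param alpha Per-iteration significance level (default 0.05).
#' @param replace Draw subsamples with replacement (bootstrap) instead of
#'   without (default `FALSE`).
#' @param seed Integer seed controlling the subsample stream.
#' @param group Label for the network (e.g. `"diabetic"`).
#' @return A `ccn` object: list with `edges` (tibble: `food_a`, `food_b`,
#'   `weight`, `sign`, `n_iterations_significant`, `n_positive`), `nodes`
#'   (all food names, isolates included), `group`, and `params`.
#' @export
stability_edges <- function(intake, covariates, n_iter = 100,
                            subsample_frac = 0.5, r_threshold = 0.2,
                            alpha = 0.05, replace = FALSE, seed = 1L,
                            group = "group") {
  mat <- intake_to_matrix(intake)
  n <- nrow(mat)
  p <- ncol(mat)
  if (p < 2) stop_dccn("Need at least two food columns.", "dccn_input_error")
  m <- floor(n * subsample_frac)
  if (m < 2 / subsample_frac) {
    stop_dccn(
      sprintf("Group too small: %d participants for subsample fraction %g.",
              n, subsample_frac),
      "dccn_input_error"
    )
  }
  cov_mat <- prepare_covariates(covariates, n)

  foods <- colnames(mat)
  sum_r <- matrix(0, p, p, dimnames = list(foods, foods))
  n_sig <- matrix(0L, p, p)
  n_pos <- matrix(0L, p, p)
  any_degenerate <- rep(FALSE, p)

  old_seed <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(restore_seed(old_seed), add = TRUE)
  set.seed(child_seed(seed, "subsample"))

  for (it in seq_len(n_iter)) {
    idx <- sample.int(n, m, replace = replace)
    ps <- partial_spearman_matrix(mat, cov_mat, idx)
    r <- ps$r
    pval <- r_to_p(r, ps$df)
    miss <- is.na(r)
    r[miss] <- 0
    pval[miss] <- 1
    any_degenerate <- any_degenerate | ps$degenerate
    sum_r <- sum_r + r
    n_sig <- n_sig + (pval < alpha)
    n_pos <- n_pos + (r > 0)
  }
  if (any(any_degenerate)) {
    warn(paste0(
      "Constant intake within at least one subsample for: ",
      paste(foods[any_degenerate], collapse = ", "),
      "; kept as isolated node(s)."
    ))
  }

  mean_r <- sum_r / n_iter
  keep <- upper.tri(mean_r) & abs(mean_r) > r_threshold & n_sig == n_iter
  ij <- which(keep, arr.ind = TRUE)
  edges <- tibble::tibble(
    food_a = foods[ij[, 1]],
    food_b = foods[ij[, 2]],
    weight = mean_r[keep],
    sign = ifelse(mean_r[keep] >= 0, 1L, -1L),
    n_iterations_significant = n_sig[keep],
    n_positive = n_pos[keep]
  ) |>
    dplyr::arrange(.data$food_a, .data$food_b)

  new_ccn(edges, nodes = foods, group = group,
          params = list(n_iter = n_iter, subsample_frac = subsample_frac,
                        r_threshold = r_threshold, alpha = alpha,
                        replace = replace, seed = seed, n = n))
}

restore_seed <- function(old_seed) {
  if (is.null(old_seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old_seed, envir = globalenv())
  }
}

intake_to_matrix <- function(intake) {
  df <- as.data.frame(intake)
  df$id <- NULL
  mat <- as.matrix(df)
  storage.mode(mat) <- "double"
  if (is.null(colnames(mat))) {
    stop_dccn("Intake columns must be named by food group.", "dccn_input_error")
  }
  mat
}

new_ccn <- function(edges, nodes, group, params = list()) {
  # canonical unordered-pair representation: food_a < food_b, rows sorted
  if (nrow(edges)) {
    swap <- edges$food_a > edges$food_b
    if (any(swap)) {
      tmp <- edges$food_a[swap]
      edges$food_a[swap] <- edges$food_b[swap]
      edges$food_b[swap] <- tmp
    }
    edges <- dplyr::arrange(edges, .data$food_a, .data$food_b)
  }
  structure(
    list(edges = edges, nodes = nodes, group = group, params = params),
    class = "ccn"
  )
}

#' Construct a co-consumption network from an edge table
#'
#' @param edges Tibble/data frame with columns `food_a`, `food_b`, `weight`
#'   (and optionally `sign`, `n_iterations_significant`).
#' @param nodes Character vector of all node names (isolates included);
#'   defaults to the foods appearing in `edges`.
#' @param group Network label.
#' @return A `ccn` object.
#' @export
ccn <- function(edges, nodes = NULL, group = "group") {
  edges <- tibble::as_tibble(edges)
  stopifnot(all(c("food_a", "food_b", "weight") %in% names(edges)))
  if (any(edges$food_a == edges$food_b)) {
    stop_dccn("Self-loops are not allowed.", "dccn_input_error")
  }
  if (!"sign" %in% names(edges)) {
    edges$sign <- ifelse(edges$weight >= 0, 1L, -1L)
  }
  if (!"n_iterations_significant" %in% names(edges)) {
    edges$n_iterations_significant <- NA_integer_
  }
  nodes <- nodes %||% sort(unique(c(edges$food_a, edges$food_b)))
  missing_nodes <- setdiff(unique(c(edges$food_a, edges$food_b)), nodes)
  if (length(missing_nodes)) {
    stop_dccn(paste0("Edge endpoints missing from `nodes`: ",
                     paste(missing_nodes, collapse = ", ")),
              "dccn_input_error")
  }
  new_ccn(edges, nodes = nodes, group = group)
}

#' @export
print.ccn <- function(x, ...) {
  cat(sprintf("<co-consumption network: %s>\n", x$group))
  cat(sprintf("  %d nodes, %d edges (%d positive, %d negative)\n",
              length(x$nodes), nrow(x$edges),
              sum(x$edges$sign > 0), sum(x$edges$sign < 0)))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a co-consumption network into its edge table
#' @param x A `ccn` object.
#' @param ... Unused.
#' @return The edge tibble.
#' @method tidy ccn
#' @export
tidy.ccn <- function(x, ...) x$edges

#' One-row summary of a co-consumption network
#' @param x A `ccn` object.
#' @param ... Unused.
#' @return A one-row tibble with node/edge counts and the graph summary
#'   statistics of [graph_summary()].
#' @method glance ccn
#' @export
glance.ccn <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(group = x$group), graph_summary(x))
}

#' Convert a co-consumption network to an igraph graph
#'
#' Edge attribute `weight` carries the signed mean correlation; shortest-path
#' computations downstream use `1/|weight|` as the distance.
#'
#' @param x A `ccn` object.
#' @return An undirected [igraph::igraph] graph including isolated nodes.
#' @export
as_igraph <- function(x) {
  stopifnot(inherits(x, "ccn"))
  igraph::graph_from_data_frame(
    x$edges[, c("food_a", "food_b", "weight")],
    directed = FALSE,
    vertices = data.frame(name = x$nodes)
  )
}

#' Sensitivity of the retained edge set to threshold and iteration count
#'
#' Re-runs [stability_edges()] over a grid of `r_threshold` and `n_iter`
#' values and reports the Jaccard overlap of each edge set with the edge set
#' at the default configuration (first computing the default itself).
#'
#' @inheritParams stability_edges
#' @param r_thresholds Numeric vector of retention thresholds.
#' @param n_iters Integer vector of iteration counts.
#' @param ... Passed on to [stability_edges()].
#' @return A tibble with `r_threshold`, `n_iter`, `n_edges`,
#'   `jaccard_vs_default`.
#' @export
threshold_sensitivity <- function(intake, covariates,
                                  r_thresholds = c(0.15, 0.2, 0.25, 0.3),
                                  n_iters = 100, seed = 1L, ...) {
  default <- stability_edges(intake, covariates, n_iter = 100,
                             r_threshold = 0.2, seed = seed, ...)
  ref <- edge_key(default$edges$food_a, default$edges$food_b)
  grid <- tidyr::expand_grid(r_threshold = r_thresholds, n_iter = n_iters)
  purrr::pmap_dfr(grid, function(r_threshold, n_iter) {
    net <- stability_edges(intake, covariates, n_iter = n_iter,
                           r_threshold = r_threshold, seed = seed, ...)
    keys <- edge_key(net$edges$food_a, net$edges$food_b)
    uni <- length(union(ref, keys))
    tibble::tibble(
      r_threshold = r_threshold, n_iter = n_iter,
      n_edges = nrow(net$edges),
      jaccard_vs_default = if (uni == 0) 1 else
        length(intersect(ref, keys)) / uni
    )
  })
}
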