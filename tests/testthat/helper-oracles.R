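# Independent oracles, written against first principles, used to check the
# package implementations. These deliberately avoid the package's internals.

# Partial Spearman correlation by explicit normal-equations residualization
# of ranks (no qr(), no lm()).
oracle_partial_spearman <- function(x, y, covariates = NULL) {
  rx <- rank(x)
  ry <- rank(y)
  X <- matrix(1, length(x), 1)
  if (!is.null(covariates)) {
    Z <- as.matrix(as.data.frame(covariates))
    X <- cbind(X, apply(Z, 2, rank))
  }
  beta_x <- solve(t(X) %*% X, t(X) %*% rx)
  beta_y <- solve(t(X) %*% X, t(X) %*% ry)
  ex <- rx - X %*% beta_x
  ey <- ry - X %*% beta_y
  sum(ex * ey) / sqrt(sum(ex^2) * sum(ey^2))
}

# Brute-force weighted betweenness: all-pairs shortest-path distances by
# Floyd-Warshall, shortest-path counts and per-vertex pass-through counts by
# dynamic programming over distance order. `dist_mat` holds edge distances
# (Inf where no edge). Returns betweenness normalized by (N-1)(N-2)/2.
oracle_betweenness <- function(dist_mat) {
  n <- nrow(dist_mat)
  d <- dist_mat
  diag(d) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  eps <- 1e-12
  # sig[s, t]: number of distinct shortest paths s -> t
  sig <- matrix(0, n, n)
  for (s in seq_len(n)) {
    sigma <- numeric(n)
    sigma[s] <- 1
    for (v in order(d[s, ])) {
      if (v == s || !is.finite(d[s, v])) next
      for (u in seq_len(n)) {
        if (is.finite(dist_mat[u, v]) &&
            abs(d[s, u] + dist_mat[u, v] - d[s, v]) < eps) {
          sigma[v] <- sigma[v] + sigma[u]
        }
      }
    }
    sig[s, ] <- sigma
  }
  bt <- numeric(n)
  for (s in seq_len(n)) {
    for (t in seq_len(n)) {
      if (t <= s || !is.finite(d[s, t])) next
      for (v in seq_len(n)) {
        if (v == s || v == t) next
        if (abs(d[s, v] + d[v, t] - d[s, t]) < eps) {
          bt[v] <- bt[v] + sig[s, v] * sig[v, t] / sig[s, t]
        }
      }
    }
  }
  bt / ((n - 1) * (n - 2) / 2)
}

# Random connected weighted ccn on n nodes: a spanning path plus extra edges.
random_weighted_ccn <- function(n_nodes = 20, extra = 15, seed = 1) {
  set.seed(seed)
  nodes <- sprintf("n%02d", seq_len(n_nodes))
  path <- tibble::tibble(food_a = nodes[-n_nodes], food_b = nodes[-1])
  pool <- t(utils::combn(nodes, 2))
  pool_keys <- paste(pool[, 1], pool[, 2])
  path_keys <- paste(path$food_a, path$food_b)
  avail <- which(!pool_keys %in% path_keys)
  pick <- sample(avail, min(extra, length(avail)))
  edges <- dplyr::bind_rows(
    path, tibble::tibble(food_a = pool[pick, 1], food_b = pool[pick, 2])
  )
  edges$weight <- runif(nrow(edges), 0.2, 1) *
    sample(c(-1, 1), nrow(edges), replace = TRUE)
  ccn(edges, nodes = nodes, group = "random")
}

# Distance matrix (1/|w|) of a ccn, Inf off-edges, for the brute-force oracle.
ccn_dist_matrix <- function(net) {
  n <- length(net$nodes)
  m <- matrix(Inf, n, n, dimnames = list(net$nodes, net$nodes))
  for (i in seq_len(nrow(net$edges))) {
    a <- net$edges$food_a[i]
    b <- net$edges$food_b[i]
    m[a, b] <- m[b, a] <- 1 / abs(net$edges$weight[i])
  }
  m
}

# Tiny two-visit cohort fixture used across data-io tests.
toy_cohort <- function() {
  visits <- tibble::tibble(
    id = rep(c("a", "b", "c"), each = 2),
    visit = rep(1:2, 3),
    energy = c(1500, 1550, 1800, 1750, 1600, 1650),
    food_rice = c(1, 2, 3, 3, 2, 4),
    food_veg = c(0.5, 0.7, 0.2, 0.4, 0.9, 1.1)
  )
  cohort <- tibble::tibble(
    id = c("a", "b", "c"),
    sex = c(1, 0, 1),
    age = c(55, 60, 48),
    education_high = c(1, 0, 1),
    exercise_regular = c(0, 1, 0),
    smoking = c("never", "current", "former"),
    alcohol = c(0, 10, 5),
    bmi = c(23, 26, 22),
    fbg_baseline = c(90, 100, 95),
    on_antidiabetic_meds = c(FALSE, FALSE, FALSE),
    person_years = c(5, 6, 7),
    incident_t2d = c(0L, 1L, 0L),
    diagnosis_visit = c(NA_integer_, 3L, NA_integer_)
  )
  list(intake = visits, cohort = cohort)
}
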