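#' @importFrom rlang %||% abort warn .data
#' @importFrom stats quantile cor qnorm pnorm qlnorm plnorm pt rbinom rgamma
#'   rnorm runif sd median glm poisson coef vcov model.matrix complete.cases
#'   setNames
#' @importFrom utils head
NULL

# Derive a reproducible child seed from a master seed and a stage label.
# Fixed offsets keep stages independently re-runnable; result stays < 2^31.
child_seed <- function(seed, stage) {
  offsets <- c(
    intake = 11L, outcome = 23L, network = 37L, subsample = 53L,
    coverage = 71L, replicate = 89L
  )
  off <- offsets[[stage]]
  (as.integer(seed) %% 1000000L) * 1000L + off
}

#' Linear-interpolation percentile
#'
#' Thin wrapper around [stats::quantile()] type 7 (linear interpolation on
#' sorted values), the estimator used everywhere in this package for energy
#' trimming, adaptive binarization cut-points and score quartiles.
#'
#' @param x Numeric vector.
#' @param probs Probabilities in `[0, 1]`.
#' @return Numeric vector of percentiles.
#' @export
pctl <- function(x, probs) {
  unname(quantile(x, probs = probs, type = 7, names = FALSE, na.rm = FALSE))
}

# Sorted two-column matrix of unordered food pairs -> canonical edge key.
edge_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

stop_dccn <- function(msg, class) {
  abort(msg, class = c(class, "dccn_error"))
}
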