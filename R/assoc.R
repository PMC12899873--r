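#' Quartile assignment for D_CCN scores
#'
#' Cuts scores at their 25th/50th/75th linear-interpolation percentiles into
#' the intervals `(-Inf, q25]`, `(q25, q50]`, `(q50, q75]`, `(q75, Inf)`
#' (closed on the right, so boundary ties fall in the lower quartile), and
#' reports the within-quartile medians used for the trend test.
#'
#' @param scores Numeric vector with at least four distinct values.
#' @return List with `labels` (factor `Q1`-`Q4` per observation), `breaks`
#'   (the three cut percentiles) and `medians` (tibble: `quartile`,
#'   `median`, `n`).
#' @export
assign_quartiles <- function(scores) {
  if (length(unique(scores)) < 4) {
    stop_dccn("Need at least 4 distinct score values to form quartiles.",
              "dccn_input_error")
  }
  br <- pctl(scores, c(0.25, 0.5, 0.75))
  labels <- cut(scores, breaks = c(-Inf, br, Inf),
                labels = paste0("Q", 1:4), right = TRUE)
  med <- tibble::tibble(quartile = labels, score = scores) |>
    dplyr::group_by(.data$quartile) |>
    dplyr::summarise(median = median(.data$score), n = dplyr::n(),
                     .groups = "drop")
  list(labels = labels, breaks = br, medians = med)
}

#' Modified Poisson regression with robust variance
#'
#' Fits a Poisson GLM to a binary incident outcome with a log person-time
#' offset (so exponentiated coefficients are incidence rate ratios), then
#' replaces the model-based variance with the HC0 sandwich estimator (bread:
#' inverse Fisher information; meat: outer product of score contributions).
#' 95\% confidence intervals use the 1.96 normal quantile on the log scale.
#'
#' @param formula Model formula for the linear predictor, e.g.
#'   `incident ~ quartile + age + sex`. Do not put the offset in the
#'   formula; it is supplied via `person_years`.
#' @param data Data frame containing the outcome, exposure and covariates.
#' @param person_years Column name (string) holding follow-up person-years;
#'   `log(person_years)` enters as the offset.
#' @param hc Sandwich flavor, `"HC0"` (default) or `"HC1"`.
#' @return A `dccn_poisson` object wrapping the glm fit, the robust
#'   covariance, and a per-term IRR table (see [tidy.dccn_poisson()]).
#' @export
modified_poisson <- function(formula, data, person_years = "person_years",
                             hc = c("HC0", "HC1")) {
  hc <- match.arg(hc)
  data <- as.data.frame(data)
  if (!person_years %in% names(data)) {
    stop_dccn(sprintf("Column '%s' not found in `data`.", person_years),
              "dccn_input_error")
  }
  py <- data[[person_years]]
  if (any(!is.finite(log(py)))) {
    stop_dccn("Person-years must be positive and finite (log offset).",
              "dccn_input_error")
  }
  data$.log_py <- log(py)
  fit <- glm(stats::update(formula, . ~ . + offset(.log_py)),
             data = data, family = poisson(link = "log"))
  if (!fit$converged) {
    stop_dccn(sprintf(
      "Poisson IRLS did not converge in %d iterations (deviance %.4g).",
      fit$iter, fit$deviance
    ), "dccn_convergence_error")
  }
  if (any(is.na(coef(fit)))) {
    stop_dccn(paste0("Rank-deficient design; aliased term(s): ",
                     paste(names(coef(fit))[is.na(coef(fit))],
                           collapse = ", ")),
              "dccn_input_error")
  }
  vc <- sandwich::vcovHC(fit, type = hc)
  b <- coef(fit)
  se <- sqrt(diag(vc))
  irr <- tibble::tibble(
    term = names(b),
    estimate = unname(b),
    robust_se = unname(se),
    irr = exp(unname(b)),
    conf_low = exp(unname(b) - 1.96 * unname(se)),
    conf_high = exp(unname(b) + 1.96 * unname(se)),
    p_value = 2 * pnorm(-abs(unname(b) / unname(se)))
  )
  structure(
    list(fit = fit, robust_vcov = vc, irr = irr, hc = hc,
         n = nrow(data), events = sum(fit$y)),
    class = "dccn_poisson"
  )
}

#' @export
print.dccn_poisson <- function(x, ...) {
  cat(sprintf(
    "<modified Poisson fit: %d participants, %d events, %s robust SE>\n",
    x$n, x$events, x$hc
  ))
  print(x$irr)
  invisible(x)
}

#' Tidy a modified Poisson fit
#' @param x A `dccn_poisson` object.
#' @param ... Unused.
#' @return Tibble with `term`, `estimate` (log IRR), `robust_se`, `irr`,
#'   `conf_low`, `conf_high`, `p_value`.
#' @method tidy dccn_poisson
#' @export
tidy.dccn_poisson <- function(x, ...) x$irr

#' One-row summary of a modified Poisson fit
#' @param x A `dccn_poisson` object.
#' @param ... Unused.
#' @return Tibble with `n`, `events`, `deviance`, `aic`, `converged`.
#' @method glance dccn_poisson
#' @export
glance.dccn_poisson <- function(x, ...) {
  tibble::tibble(n = x$n, events = x$events,
                 deviance = x$fit$deviance, aic = x$fit$aic,
                 converged = x$fit$converged)
}

#' Quartile IRRs and median-scored trend test
#'
#' Convenience wrapper for the full association analysis: assigns score
#' quartiles, fits the quartile model (Q1 reference), and refits the same
#' model with each quartile replaced by its median score as a single
#' continuous term, whose robust Wald p-value is the trend p.
#'
#' @param data Data frame with the outcome, person-years and covariates.
#' @param score Column name (string) of the D_CCN score.
#' @param outcome Column name of the 0/1 incident-outcome flag.
#' @param covariates Character vector of adjustment covariate column names
#'   (may be empty).
#' @param person_years Person-years column name.
#' @param hc Sandwich flavor passed to [modified_poisson()].
#' @return List with `quartile_fit` and `trend_fit` (`dccn_poisson`
#'   objects), `quartiles` (from [assign_quartiles()]), `irr` (quartile IRR
#'   rows only, reference included), and `p_trend`.
#' @export
quartile_irr <- function(data, score = "d_ccn", outcome = "incident_t2d",
                         covariates = character(), person_years = "person_years",
                         hc = "HC0") {
  data <- as.data.frame(data)
  q <- assign_quartiles(data[[score]])
  data$.quartile <- q$labels
  med_map <- setNames(q$medians$median, as.character(q$medians$quartile))
  data$.trend <- med_map[as.character(q$labels)]
  if (length(unique(data$.trend)) < 2) {
    stop_dccn("Trend variable is constant across quartiles.",
              "dccn_input_error")
  }
  rhs <- paste(c(".quartile", covariates), collapse = " + ")
  qfit <- modified_poisson(
    stats::as.formula(paste(outcome, "~", rhs)), data,
    person_years = person_years, hc = hc
  )
  rhs_t <- paste(c(".trend", covariates), collapse = " + ")
  tfit <- modified_poisson(
    stats::as.formula(paste(outcome, "~", rhs_t)), data,
    person_years = person_years, hc = hc
  )
  trend_row <- tfit$irr[tfit$irr$term == ".trend", ]
  irr <- dplyr::bind_rows(
    tibble::tibble(term = "Q1", estimate = 0, robust_se = 0, irr = 1,
                   conf_low = 1, conf_high = 1, p_value = NA_real_),
    dplyr::mutate(
      dplyr::filter(qfit$irr, grepl("^\\.quartileQ", .data$term)),
      term = sub("^\\.quartile", "", .data$term)
    )
  )
  list(quartile_fit = qfit, trend_fit = tfit, quartiles = q,
       irr = irr, p_trend = trend_row$p_value)
}

#' Robust Wald trend test over quartile medians
#'
#' @param data Data frame with outcome, person-years and covariates.
#' @inheritParams quartile_irr
#' @return Two-sided robust Wald p-value for the median-scored continuous
#'   quartile term.
#' @export
trend_test <- function(data, score = "d_ccn", outcome = "incident_t2d",
                       covariates = character(),
                       person_years = "person_years", hc = "HC0") {
  quartile_irr(data, score = score, outcome = outcome,
               covariates = covariates, person_years = person_years,
               hc = hc)$p_trend
}
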