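#' Baseline exclusion filters
#'
#' Removes, in fixed order with one recorded reason per participant:
#' \enumerate{
#'   \item prevalent diabetes at baseline — anti-diabetic medication or
#'     fasting blood glucose >= 126 mg/dL (`"prevalent_diabetes"`);
#'   \item implausible dietary data — baseline energy at or beyond the
#'     0.5th / 99.5th percentile of baseline energy within the input cohort
#'     (`"energy_outlier"`);
#'   \item any missing key covariate among education, exercise, smoking,
#'     alcohol and BMI (`"missing_covariate"`).
#' }
#' The energy band actually applied is recorded as an attribute of the
#' returned cohort and reused verbatim when the function is re-applied to
#' its own output, so exclusion is idempotent.
#'
#' @param cohort Participant tibble with at least `id`,
#'   `on_antidiabetic_meds`, `fbg_baseline` and the key covariates.
#' @param intake Visit-level intake tibble with `id`, `visit`, `energy`;
#'   baseline = smallest visit index per participant.
#' @param energy_low_pct,energy_high_pct Percentile bounds (default
#'   0.005 / 0.995), linear-interpolation estimator; `0` / `1` disable the
#'   corresponding bound.
#' @return List with `cohort` (retained rows, energy band attached as
#'   attribute `energy_band`) and `log` (tibble `id`, `reason`).
#' @export
apply_exclusions <- function(cohort, intake, energy_low_pct = 0.005,
                             energy_high_pct = 0.995) {
  band <- attr(cohort, "energy_band")
  cohort <- tibble::as_tibble(cohort)
  baseline <- intake |>
    dplyr::group_by(.data$id) |>
    dplyr::slice_min(.data$visit, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
  energy <- setNames(baseline$energy, baseline$id)[cohort$id]

  prevalent <- (!is.na(cohort$on_antidiabetic_meds) & cohort$on_antidiabetic_meds) |
    (!is.na(cohort$fbg_baseline) & cohort$fbg_baseline >= 126)

  if (is.null(band)) {
    e_ok <- energy[!is.na(energy)]
    band <- c(
      if (energy_low_pct > 0) pctl(e_ok, energy_low_pct) else -Inf,
      if (energy_high_pct < 1) pctl(e_ok, energy_high_pct) else Inf
    )
  }
  energy_out <- is.na(energy) | energy <= band[1] | energy >= band[2]

  key_cov <- intersect(
    c("education_high", "exercise_regular", "smoking", "alcohol", "bmi"),
    names(cohort)
  )
  missing_cov <- if (length(key_cov)) {
    rowSums(is.na(as.data.frame(cohort[key_cov]))) > 0
  } else {
    rep(FALSE, nrow(cohort))
  }

  reason <- dplyr::case_when(
    prevalent ~ "prevalent_diabetes",
    energy_out ~ "energy_outlier",
    missing_cov ~ "missing_covariate",
    TRUE ~ NA_character_
  )
  keep <- is.na(reason)
  if (!any(keep)) {
    stop_dccn("All participants excluded; check the input cohort.",
              "dccn_empty_cohort_error")
  }
  retained <- cohort[keep, ]
  attr(retained, "energy_band") <- band
  list(
    cohort = retained,
    log = tibble::tibble(id = cohort$id[!keep], reason = reason[!keep])
  )
}

#' Cumulative-average intake before diagnosis or censoring
#'
#' Averages repeated dietary assessments per participant, using only visits
#' that precede the diabetes diagnosis:
#' \describe{
#'   \item{`multi_visit`}{mean over all visits strictly before the
#'     diagnosis visit (all visits if never diagnosed);}
#'   \item{`baseline_plus_one`}{baseline only if the diagnosis precedes the
#'     single follow-up dietary assessment (visit 2), else the mean of
#'     both assessments.}
#' }
#'
#' @param intake Visit-level tibble: `id`, `visit` (ordered integer,
#'   1 = baseline), `energy`, plus one column per food.
#' @param cohort Participant tibble with `id` and `diagnosis_visit`
#'   (`NA` when never diagnosed).
#' @param design `"multi_visit"` or `"baseline_plus_one"`.
#' @return Tibble with one row per participant: `id`, averaged `energy`,
#'   averaged food columns.
#' @export
cumulative_average <- function(intake, cohort,
                               design = c("multi_visit", "baseline_plus_one")) {
  design <- match.arg(design)
  intake <- tibble::as_tibble(intake)
  dv <- setNames(cohort$diagnosis_visit, cohort$id)
  cutoff <- dv[intake$id]
  eligible <- switch(design,
    multi_visit = is.na(cutoff) | intake$visit < cutoff,
    baseline_plus_one = {
      diagnosed_early <- !is.na(cutoff) & cutoff <= 2
      !diagnosed_early | intake$visit == 1
    }
  )
  kept <- intake[eligible & intake$id %in% cohort$id, ]
  lost <- setdiff(cohort$id, kept$id)
  if (length(lost)) {
    stop_dccn(paste0("No eligible dietary visit for participant(s): ",
                     paste(head(lost, 5), collapse = ", ")),
              "dccn_input_error")
  }
  kept |>
    dplyr::select(-"visit") |>
    dplyr::group_by(.data$id) |>
    dplyr::summarise(dplyr::across(dplyr::where(is.numeric), mean),
                     .groups = "drop")
}

#' Read a cohort table from delimited text
#'
#' One row per participant-visit. Food columns are identified by prefix
#' (default `"food_"`) or an explicit list.
#'
#' @param path CSV file path.
#' @param food_prefix Prefix identifying food columns.
#' @param food_cols Optional explicit character vector of food columns;
#'   overrides the prefix.
#' @return List with `cohort` (one row per participant: covariates from the
#'   baseline row) and `intake` (`id`, `visit`, `energy`, food columns).
#' @export
read_cohort <- function(path, food_prefix = "food_", food_cols = NULL) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("id", "visit") %in% names(df))) {
    stop_dccn("Cohort file must contain 'id' and 'visit' columns.",
              "dccn_io_error")
  }
  foods <- food_cols %||% grep(paste0("^", food_prefix), names(df),
                               value = TRUE)
  unknown <- setdiff(foods, names(df))
  if (length(unknown)) {
    stop_dccn(paste0("Unknown food column(s): ",
                     paste(unknown, collapse = ", ")),
              "dccn_io_error")
  }
  if (!length(foods)) {
    stop_dccn("No food columns found.", "dccn_io_error")
  }
  neg <- foods[purrr::map_lgl(df[foods], ~ any(.x < 0, na.rm = TRUE))]
  if (length(neg)) {
    stop_dccn(paste0("Negative intake in column(s): ",
                     paste(neg, collapse = ", ")),
              "dccn_io_error")
  }
  dup <- df |>
    dplyr::count(.data$id, .data$visit) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup)) {
    stop_dccn(paste0("Duplicate participant-visit row(s): ",
                     paste(head(dup$id, 5), collapse = ", ")),
              "dccn_io_error")
  }
  intake_cols <- c("id", "visit",
                   intersect("energy", names(df)), foods)
  cohort <- df |>
    dplyr::group_by(.data$id) |>
    dplyr::slice_min(.data$visit, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::select(-dplyr::all_of(setdiff(intake_cols, "id")))
  list(cohort = cohort, intake = df[, intake_cols])
}

#' Write / read a co-consumption network
#'
#' `edge_csv` writes the edge table with columns `food_a`, `food_b`,
#' `weight`, `sign`, `n_iterations_significant`; `graphml` writes the full
#' graph (isolated nodes included) via igraph.
#'
#' @param net A `ccn` object.
#' @param path Output file path.
#' @param format `"edge_csv"` (default) or `"graphml"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, format = c("edge_csv", "graphml")) {
  format <- match.arg(format)
  stopifnot(inherits(net, "ccn"))
  if (format == "edge_csv") {
    readr::write_csv(
      net$edges[, c("food_a", "food_b", "weight", "sign",
                    "n_iterations_significant")],
      path
    )
  } else {
    igraph::write_graph(as_igraph(net), path, format = "graphml")
  }
  invisible(path)
}

#' @rdname write_network
#' @param nodes Optional node universe for `read_network()` (edge CSVs do
#'   not carry isolates); defaults to the foods appearing in the edges.
#' @param group Network label for the reconstructed object.
#' @export
read_network <- function(path, nodes = NULL, group = "group",
                         format = c("edge_csv", "graphml")) {
  format <- match.arg(format)
  if (format == "edge_csv") {
    edges <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
    ccn(edges, nodes = nodes, group = group)
  } else {
    g <- igraph::read_graph(path, format = "graphml")
    edges <- igraph::as_data_frame(g, what = "edges")
    ccn(tibble::tibble(food_a = edges$from, food_b = edges$to,
                       weight = edges$weight %||% rep(1, nrow(edges))),
        nodes = igraph::V(g)$name, group = group)
  }
}

#' Write / read a score table
#'
#' @param scores Score tibble from [score_dccn()].
#' @param path CSV path.
#' @return `path` invisibly (write); the score tibble (read).
#' @export
write_scores <- function(scores, path) {
  readr::write_csv(scores, path)
  invisible(path)
}

#' @rdname write_scores
#' @export
read_scores <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                  col_types = readr::cols(id = readr::col_character()))
}

#' Write an exclusion log as JSON
#'
#' @param log Exclusion log tibble (`id`, `reason`).
#' @param path JSON path.
#' @return `path`, invisibly.
#' @export
write_exclusion_log <- function(log, path) {
  jsonlite::write_json(log, path, dataframe = "rows", auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}
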