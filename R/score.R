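#' Adaptive binarization cut-points
#'
#' Dietary intake is zero-inflated and right-skewed, so a single quantile
#' rule cannot separate consumers from non-consumers for every food. The
#' cut-point for each food is chosen hierarchically from its own
#' distribution (quartiles by linear interpolation):
#' \enumerate{
#'   \item if the first quartile (Q1) is non-zero, Q1 is the cut-point;
#'   \item if Q1 is zero but the median is positive, the median;
#'   \item if Q1 and the median are zero, the third quartile (Q3);
#'   \item if all three quartiles are zero, any amount above zero counts as
#'     consumption.
#' }
#'
#' @param intake Data frame or matrix of cumulative-average intakes
#'   (participants x foods, servings/day); a column named `id` is ignored.
#' @return A tibble with columns `food`, `cutpoint`, `rule`
#'   (`Q1`, `median`, `Q3`, `any_positive`).
#' @export
adaptive_cutpoints <- function(intake) {
  mat <- intake_to_matrix(intake)
  if (nrow(mat) == 0) {
    stop_dccn("Empty intake table.", "dccn_input_error")
  }
  purrr::map_dfr(colnames(mat), function(f) {
    x <- mat[, f]
    if (all(is.na(x))) {
      stop_dccn(sprintf("Food column '%s' is empty.", f), "dccn_input_error")
    }
    q <- pctl(x, c(0.25, 0.5, 0.75))
    if (q[1] > 0) {
      tibble::tibble(food = f, cutpoint = q[1], rule = "Q1")
    } else if (q[2] > 0) {
      tibble::tibble(food = f, cutpoint = q[2], rule = "median")
    } else if (q[3] > 0) {
      tibble::tibble(food = f, cutpoint = q[3], rule = "Q3")
    } else {
      tibble::tibble(food = f, cutpoint = 0, rule = "any_positive")
    }
  })
}

#' Binarize intakes against adaptive cut-points
#'
#' A cell is 1 iff the intake is strictly above the food's cut-point
#' (for `any_positive` foods, strictly above zero). Values equal to the
#' cut-point are coded 0 ("not consumed") — this matters for staple foods
#' with heavy ties at the median.
#'
#' @param intake Intake table (participants x foods); `id` column preserved
#'   if present.
#' @param cutpoints Tibble from [adaptive_cutpoints()] covering every food
#'   column of `intake`.
#' @return Tibble of 0/1 integers with the same food columns (and `id` if
#'   supplied).
#' @export
binarize <- function(intake, cutpoints) {
  df <- tibble::as_tibble(as.data.frame(intake))
  id <- df[["id"]]
  df$id <- NULL
  missing <- setdiff(names(df), cutpoints$food)
  if (length(missing)) {
    stop_dccn(paste0("No cut-point for food(s): ",
                     paste(missing, collapse = ", ")),
              "dccn_input_error")
  }
  cut <- setNames(cutpoints$cutpoint, cutpoints$food)
  out <- purrr::imap_dfc(df, function(x, f) as.integer(x > cut[[f]]))
  if (!is.null(id)) out <- dplyr::bind_cols(tibble::tibble(id = id), out)
  out
}

#' D_CCN scores from binarized intake and subnetwork weights
#'
#' The Diabetes (Non-diabetes) Score of a participant is the sum of the
#' integrated centrality weights of the diabetes-specific (non-diabetes-
#' specific) differential subnetwork over the foods the participant
#' consumes; foods absent from a subnetwork contribute 0 to that score. The
#' D_CCN score is their difference (Diabetes Score − Non-diabetes Score):
#' higher values mean the diet aligns more with the diabetes-specific
#' co-consumption structure.
#'
#' @param binary Binarized intake tibble from [binarize()] (optionally with
#'   an `id` column).
#' @param weights_diabetic,weights_nondiabetic Named numeric vectors or
#'   two-column tibbles (`food`, `integrated_centrality`) of subnetwork
#'   weights.
#' @return A tibble with `id`, `diabetes_score`, `non_diabetes_score`,
#'   `d_ccn`.
#' @export
score_dccn <- function(binary, weights_diabetic, weights_nondiabetic) {
  df <- tibble::as_tibble(binary)
  id <- df[["id"]] %||% seq_len(nrow(df))
  df$id <- NULL
  w_d <- as_weight_vector(weights_diabetic)
  w_nd <- as_weight_vector(weights_nondiabetic)
  unknown <- setdiff(c(names(w_d), names(w_nd)), names(df))
  if (length(unknown)) {
    stop_dccn(paste0("Weight map references unknown food(s): ",
                     paste(sort(unique(unknown)), collapse = ", ")),
              "dccn_input_error")
  }
  mat <- as.matrix(df)
  score_with <- function(w) {
    if (!length(w)) return(rep(0, nrow(mat)))
    as.numeric(mat[, names(w), drop = FALSE] %*% w)
  }
  ds <- score_with(w_d)
  nds <- score_with(w_nd)
  tibble::tibble(id = id, diabetes_score = ds, non_diabetes_score = nds,
                 d_ccn = ds - nds)
}

as_weight_vector <- function(w) {
  if (is.data.frame(w)) {
    stopifnot(all(c("food", "integrated_centrality") %in% names(w)))
    w <- setNames(w$integrated_centrality, w$food)
  }
  if (is.null(names(w)) && length(w) > 0) {
    stop_dccn("Weights must be named by food.", "dccn_input_error")
  }
  w
}

#' Cross-cohort score transfer
#'
#' Applies subnetwork weights derived in one cohort to the intake of
#' another: cut-points are recomputed within the target cohort's own
#' distribution, while the weights stay those of the source cohort. Under
#' `policy = "strict"` any weighted food missing from the target intake is
#' an error; under `"drop_missing"` the term is skipped with a warning.
#'
#' @param intake Target-cohort intake table (participants x foods,
#'   optional `id`).
#' @param weights_diabetic,weights_nondiabetic Source-cohort weight maps
#'   (named vectors or `food`/`integrated_centrality` tibbles).
#' @param policy `"strict"` (default) or `"drop_missing"`.
#' @param harmonize Optional named character vector mapping source food
#'   names to target food names.
#' @return Score tibble as from [score_dccn()].
#' @export
transfer_scores <- function(intake, weights_diabetic, weights_nondiabetic,
                            policy = c("strict", "drop_missing"),
                            harmonize = NULL) {
  policy <- match.arg(policy)
  df <- tibble::as_tibble(as.data.frame(intake))
  foods <- setdiff(names(df), "id")
  rename_w <- function(w) {
    w <- as_weight_vector(w)
    if (!is.null(harmonize)) {
      hit <- names(w) %in% names(harmonize)
      names(w)[hit] <- harmonize[names(w)[hit]]
    }
    missing <- setdiff(names(w), foods)
    if (length(missing)) {
      if (policy == "strict") {
        stop_dccn(paste0("Weighted food(s) absent from target cohort: ",
                         paste(missing, collapse = ", ")),
                  "dccn_transfer_error")
      }
      warn(paste0("Dropping weighted food(s) absent from target cohort: ",
                  paste(missing, collapse = ", ")))
      w <- w[!names(w) %in% missing]
    }
    w
  }
  w_d <- rename_w(weights_diabetic)
  w_nd <- rename_w(weights_nondiabetic)
  cp <- adaptive_cutpoints(df)
  score_dccn(binarize(df, cp), w_d, w_nd)
}
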