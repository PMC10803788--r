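#' Stage 1: aggregate a decision tensor over time
#'
#' Collapses the period dimension of a temporal decision tensor: each
#' (alternative, attribute) cell's series of `p` pairs is pooled with the
#' dynamic weighted averaging or geometric operator into one pair, yielding
#' the collective decision matrix.
#'
#' @param tensor An [ff_tensor()] (or any data frame with `alternative`,
#'   `attribute`, `period`, `mu`, `nu` columns).
#' @param eps Time weights; defaults to the tensor's attached
#'   [time_weights()].
#' @param variant `"averaging"` (FFDyWA / IFDWA) or `"geometric"`
#'   (FFDyWG / IFDWG).
#' @param q Constraint exponent: 3 for the Fermatean operators, 1 for the
#'   intuitionistic baselines.
#' @param normalize Passed to [ff_weights()].
#' @return A tibble with one row per (alternative, attribute) and columns
#'   `mu`, `nu`, in tensor label order.
#' @examples
#' aggregate_time(all_treatment(), variant = "averaging")
#' @export
aggregate_time <- function(tensor, eps = NULL,
                           variant = c("averaging", "geometric"),
                           q = 3, normalize = FALSE) {
  variant <- rlang::arg_match(variant)
  eps <- eps %||% time_weights(tensor)
  if (is.null(eps)) {
    rlang::abort("time weights: supply `eps` or a tensor carrying time weights.",
                 class = "fermadm_invalid_weights")
  }
  eps <- ff_weights(eps, normalize = normalize, label = "time")
  pers <- attr(tensor, "periods") %||% unique(as.character(tensor$period))
  alts <- attr(tensor, "alternatives") %||% unique(as.character(tensor$alternative))
  atts <- attr(tensor, "attributes") %||% unique(as.character(tensor$attribute))
  if (length(eps) != length(pers)) {
    rlang::abort(
      sprintf("time weights: got %d weights for %d periods.",
              length(eps), length(pers)),
      class = "fermadm_length_mismatch"
    )
  }
  tensor |>
    dplyr::mutate(.k = match(.data$period, pers)) |>
    dplyr::arrange(match(.data$alternative, alts),
                   match(.data$attribute, atts), .data$.k) |>
    dplyr::group_by(.data$alternative, .data$attribute) |>
    dplyr::group_modify(function(cell, key) {
      agg_kernel(cell$mu, cell$nu, eps[cell$.k], q = q, form = variant)
    }) |>
    dplyr::ungroup() |>
    dplyr::arrange(match(.data$alternative, alts),
                   match(.data$attribute, atts))
}

#' Stage 2: aggregate the collective matrix across attributes
#'
#' Pools each alternative's row of the collective decision matrix across
#' attributes with the power-form weighted averaging or geometric operator,
#' yielding one overall pair per alternative.
#'
#' @param collective A data frame with columns `alternative`, `attribute`,
#'   `mu`, `nu` (the output of [aggregate_time()]).
#' @param omega Attribute weights, one per attribute.
#' @inheritParams aggregate_time
#' @return A tibble with one row per alternative and columns `mu`, `nu`.
#' @examples
#' all_treatment() |>
#'   aggregate_time(variant = "averaging") |>
#'   aggregate_attributes(attribute_weights(all_treatment()))
#' @export
aggregate_attributes <- function(collective, omega,
                                 variant = c("averaging", "geometric"),
                                 q = 3, normalize = FALSE) {
  variant <- rlang::arg_match(variant)
  check_pairs(collective)
  if (!all(c("alternative", "attribute") %in% names(collective))) {
    rlang::abort("`collective` needs `alternative` and `attribute` columns.",
                 class = "fermadm_error")
  }
  omega <- ff_weights(omega, normalize = normalize, label = "attribute")
  alts <- unique(as.character(collective$alternative))
  atts <- unique(as.character(collective$attribute))
  if (length(omega) != length(atts)) {
    rlang::abort(
      sprintf("attribute weights: got %d weights for %d attributes.",
              length(omega), length(atts)),
      class = "fermadm_length_mismatch"
    )
  }
  collective |>
    dplyr::mutate(.j = match(.data$attribute, atts)) |>
    dplyr::arrange(match(.data$alternative, alts), .data$.j) |>
    dplyr::group_by(.data$alternative) |>
    dplyr::group_modify(function(row, key) {
      agg_kernel(row$mu, row$nu, omega[row$.j], q = q, form = variant)
    }) |>
    dplyr::ungroup() |>
    dplyr::arrange(match(.data$alternative, alts))
}

#' Stages 3--4: score and rank the overall values
#'
#' Scores each alternative's overall pair (mu^3 - nu^3 for Fermatean pairs,
#' mu - nu for intuitionistic ones), breaks score ties by accuracy, and
#' orders the alternatives. Residual ties (score and accuracy both equal
#' within `tol`) are reported as explicit tie groups in input order rather
#' than broken arbitrarily, so plural optima remain visible.
#'
#' @param overall A data frame with columns `alternative`, `mu`, `nu` (the
#'   output of [aggregate_attributes()]).
#' @param q Exponent of the score/accuracy functions (3 Fermatean,
#'   1 intuitionistic).
#' @param tol Tie tolerance on score and accuracy.
#' @return A tibble with columns `alternative`, `mu`, `nu`, `score`,
#'   `accuracy`, `rank`, `tie_group`, sorted best-first. `rank` is the
#'   position in that sort; members of one `tie_group` share a group id.
#' @export
rank_alternatives <- function(overall, q = 3, tol = 1e-12) {
  check_pairs(overall)
  if (!"alternative" %in% names(overall) || nrow(overall) == 0L) {
    rlang::abort("`overall` needs an `alternative` column and at least one row.",
                 class = "fermadm_error")
  }
  out <- tibble::as_tibble(overall)
  out$score <- out$mu^q - out$nu^q
  out$accuracy <- out$mu^q + out$nu^q
  out$.input <- seq_len(nrow(out))
  out <- dplyr::arrange(out, dplyr::desc(.data$score),
                        dplyr::desc(.data$accuracy), .data$.input)
  # successive rows tie when both keys agree within tol
  new_group <- c(TRUE, abs(diff(out$score)) > tol | abs(diff(out$accuracy)) > tol)
  out$tie_group <- cumsum(new_group)
  # within a tie group restore original input order
  out <- dplyr::arrange(out, .data$tie_group, .data$.input)
  out$rank <- seq_len(nrow(out))
  out$.input <- NULL
  out
}

#' Run the full two-stage dynamic ranking
#'
#' End-to-end pipeline: aggregate the tensor over time ([aggregate_time()]),
#' pool across attributes ([aggregate_attributes()]), score and rank
#' ([rank_alternatives()]). `family = "fermatean"` uses the FFDyWA/FFWA
#' (averaging) or FFDyWG/FFWG (geometric) operators with cubic score;
#' `family = "intuitionistic"` runs the exponent-1 baseline operators
#' (IFDWA/IFDWG) with linear score. Fermatean data generally violate the
#' intuitionistic constraint mu + nu <= 1, so the baseline defaults to
#' permissive validation and records every violating cell in the report.
#'
#' @inheritParams aggregate_time
#' @param omega Attribute weights; defaults to the tensor's attached
#'   [attribute_weights()].
#' @param family Operator family, `"fermatean"` (default) or
#'   `"intuitionistic"`.
#' @param mode Cell validation mode; defaults to `"strict"` for the Fermatean
#'   family and `"permissive"` for the intuitionistic baseline.
#' @return An object of class `ff_decision`: a list with elements
#'   `collective`, `overall`, `ranking` (tibbles), `variant`, `family`,
#'   `violations` and the label sets. Supports `print()`,
#'   [generics::tidy()], [generics::glance()] and [ggplot2::autoplot()].
#' @examples
#' dec <- ff_decide(all_treatment(), variant = "averaging")
#' dec
#' tidy(dec)
#' @export
ff_decide <- function(tensor, eps = NULL, omega = NULL,
                      variant = c("averaging", "geometric"),
                      family = c("fermatean", "intuitionistic"),
                      mode = NULL, normalize = FALSE) {
  variant <- rlang::arg_match(variant)
  family <- rlang::arg_match(family)
  q <- if (family == "fermatean") 3 else 1
  mode <- mode %||% if (family == "fermatean") "strict" else "permissive"
  mode <- rlang::arg_match0(mode, c("strict", "permissive"))

  eps <- eps %||% time_weights(tensor)
  omega <- omega %||% attribute_weights(tensor)
  if (is.null(eps) || is.null(omega)) {
    rlang::abort(
      "both time weights (`eps`) and attribute weights (`omega`) are required.",
      class = "fermadm_invalid_weights"
    )
  }

  stage <- "validation"
  result <- tryCatch({
    revalidated <- ff_validate(tensor[, c("mu", "nu")], mode = mode, q = q)
    violations <- tibble::as_tibble(tensor)[!revalidated$valid,
                                            c("alternative", "attribute",
                                              "period", "mu", "nu")]
    stage <- "time aggregation"
    collective <- aggregate_time(tensor, eps = eps, variant = variant, q = q,
                                 normalize = normalize)
    stage <- "attribute aggregation"
    overall <- aggregate_attributes(collective, omega = omega,
                                    variant = variant, q = q,
                                    normalize = normalize)
    stage <- "ranking"
    ranking <- rank_alternatives(overall, q = q)
    list(collective = collective, overall = overall, ranking = ranking,
         violations = violations)
  }, fermadm_error = function(e) stage_abort(e, stage),
     fermadm_invalid_ffn = function(e) stage_abort(e, stage),
     fermadm_invalid_weights = function(e) stage_abort(e, stage),
     fermadm_length_mismatch = function(e) stage_abort(e, stage))

  structure(
    c(result,
      list(variant = variant, family = family, mode = mode,
           eps = eps, omega = omega,
           alternatives = attr(tensor, "alternatives") %||%
             unique(as.character(tensor$alternative)),
           attributes = attr(tensor, "attributes") %||%
             unique(as.character(tensor$attribute)),
           periods = attr(tensor, "periods") %||%
             unique(as.character(tensor$period)))),
    class = "ff_decision"
  )
}

stage_abort <- function(e, stage) {
  rlang::abort(sprintf("[stage: %s] %s", stage, conditionMessage(e)),
               class = class(e)[1], parent = e)
}

#' Format a ranking as a succession chain
#'
#' @param x An `ff_decision`.
#' @return A string such as `"X4 > X1 > X2 > X3"`, using `≻` between
#'   strictly ordered alternatives and `~` within tie groups.
#' @export
ranking_chain <- function(x) {
  stopifnot(inherits(x, "ff_decision"))
  r <- x$ranking
  groups <- split(r$alternative, r$tie_group)
  paste(vapply(groups, paste, "", collapse = " ~ "), collapse = " ≻ ")
}

#' @export
print.ff_decision <- function(x, digits = 3, ...) {
  op <- if (x$family == "fermatean") {
    if (x$variant == "averaging") "FFDyWA + FFWA" else "FFDyWG + FFWG"
  } else {
    if (x$variant == "averaging") "IFDWA" else "IFDWG"
  }
  cat(sprintf("<ff_decision> %s family, %s variant (%s)\n",
              x$family, x$variant, op))
  cat(sprintf("  %d alternatives x %d attributes x %d periods\n",
              length(x$alternatives), length(x$attributes),
              length(x$periods)))
  if (nrow(x$violations) > 0) {
    cat(sprintf("  %d cell(s) violate the %s constraint (permissive mode)\n",
                nrow(x$violations), x$family))
  }
  tab <- x$ranking
  tab$mu <- round(tab$mu, digits)
  tab$nu <- round(tab$nu, digits)
  tab$score <- round(tab$score, digits)
  tab$accuracy <- round(tab$accuracy, digits)
  print(tab, ...)
  cat("  ranking:", ranking_chain(x), "\n")
  invisible(x)
}
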