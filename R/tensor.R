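#' Build a temporal decision tensor
#'
#' A temporal decision tensor holds the evaluation of `m` alternatives against
#' `n` attributes at `p` time periods, each cell a Fermatean fuzzy pair. It is
#' stored tidily: one row per (alternative, attribute, period) cell with
#' numeric columns `mu` and `nu`. Label ordering (which drives matrix layout
#' and reporting order) follows first appearance in `data` unless the columns
#' are factors, whose level order is respected.
#'
#' @param data A data frame with columns `alternative`, `attribute`, `period`,
#'   `mu`, `nu`, containing every combination of the three labels exactly once.
#' @param time_weights,attribute_weights Optional weight vectors (validated
#'   with [ff_weights()]) carried along as attributes and used as defaults by
#'   [ff_decide()].
#' @param mode Cell validation mode, see [ffn()].
#' @param q Constraint exponent for cell validation (3 = Fermatean).
#' @param normalize Passed to [ff_weights()].
#' @return A tibble of class `ff_tensor` with attributes `alternatives`,
#'   `attributes`, `periods`, `time_weights`, `attribute_weights`.
#' @examples
#' cells <- tidyr::expand_grid(
#'   alternative = c("A", "B"), attribute = c("x", "y"), period = "t1"
#' )
#' cells$mu <- c(0.7, 0.6, 0.8, 0.5)
#' cells$nu <- c(0.4, 0.5, 0.3, 0.6)
#' ff_tensor(cells, time_weights = 1, attribute_weights = c(0.6, 0.4))
#' @export
ff_tensor <- function(data, time_weights = NULL, attribute_weights = NULL,
                      mode = c("strict", "permissive"), q = 3,
                      normalize = FALSE) {
  mode <- rlang::arg_match(mode)
  needed <- c("alternative", "attribute", "period", "mu", "nu")
  if (!is.data.frame(data) || !all(needed %in% names(data))) {
    rlang::abort(
      paste0("`data` must contain columns ",
             paste0("`", needed, "`", collapse = ", "), "."),
      class = "fermadm_error"
    )
  }
  lev <- function(x) if (is.factor(x)) levels(x) else unique(as.character(x))
  alts <- lev(data$alternative)
  atts <- lev(data$attribute)
  pers <- lev(data$period)
  data <- tibble::as_tibble(data)
  data$alternative <- as.character(data$alternative)
  data$attribute <- as.character(data$attribute)
  data$period <- as.character(data$period)

  expected <- tidyr::expand_grid(period = pers, alternative = alts,
                                 attribute = atts)
  if (nrow(data) != nrow(expected) ||
      nrow(dplyr::distinct(data, period, alternative, attribute)) != nrow(data) ||
      nrow(dplyr::anti_join(expected, data,
                            by = c("period", "alternative", "attribute"))) > 0) {
    rlang::abort(
      "every (alternative, attribute, period) combination must appear exactly once.",
      class = "fermadm_error"
    )
  }

  validated <- ff_validate(data[, c("mu", "nu")], mode = mode, q = q)
  data$valid <- validated$valid
  if (mode == "strict" && !all(data$valid)) {
    # unreachable: ff_validate aborts first in strict mode
    rlang::abort("invalid cells in strict mode.", class = "fermadm_invalid_ffn")
  }
  bad <- data[!data$valid, ]
  if (nrow(bad) > 0) {
    rlang::inform(sprintf(
      "%d cell(s) violate the exponent-%d constraint (first: alternative %s, attribute %s, period %s).",
      nrow(bad), q, bad$alternative[1], bad$attribute[1], bad$period[1]
    ))
  }

  if (!is.null(time_weights)) {
    time_weights <- ff_weights(time_weights, normalize = normalize,
                               label = "time")
    if (length(time_weights) != length(pers)) {
      rlang::abort(
        sprintf("time weights: got %d weights for %d periods.",
                length(time_weights), length(pers)),
        class = "fermadm_length_mismatch"
      )
    }
  }
  if (!is.null(attribute_weights)) {
    attribute_weights <- ff_weights(attribute_weights, normalize = normalize,
                                    label = "attribute")
    if (length(attribute_weights) != length(atts)) {
      rlang::abort(
        sprintf("attribute weights: got %d weights for %d attributes.",
                length(attribute_weights), length(atts)),
        class = "fermadm_length_mismatch"
      )
    }
  }

  data <- dplyr::arrange(
    data,
    match(period, pers), match(alternative, alts), match(attribute, atts)
  )
  structure(
    data,
    alternatives = alts,
    attributes = atts,
    periods = pers,
    time_weights = time_weights,
    attribute_weights = attribute_weights,
    q = q,
    class = c("ff_tensor", class(tibble::tibble()))
  )
}

#' @rdname ff_tensor
#' @param x An `ff_tensor`.
#' @export
time_weights <- function(x) attr(x, "time_weights")

#' @rdname ff_tensor
#' @export
attribute_weights <- function(x) attr(x, "attribute_weights")

#' The blood-cancer treatment case study tensor
#'
#' The packaged 4 x 5 x 3 decision tensor evaluating four treatment
#' modalities for acute lymphoblastic leukemia — chemotherapy, hematopoietic
#' stem-cell transplantation, radiation therapy, and CAR T-cell therapy —
#' against survival rate, remission, side effects, efficiency and reliability
#' over three two-year assessment periods (2017--2019, 2019--2021,
#' 2021--2023). Ships with its time weights (0.2, 0.3, 0.5) and attribute
#' weights (0.3, 0.25, 0.1, 0.2, 0.15).
#'
#' @return An [ff_tensor()] with weights attached.
#' @examples
#' tens <- all_treatment()
#' time_weights(tens)
#' @export
all_treatment <- function() {
  path <- system.file("extdata", "all_treatment.json", package = "fermadm",
                      mustWork = TRUE)
  read_ff_tensor(path, format = "json")
}
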