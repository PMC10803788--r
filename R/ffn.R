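#' Construct Fermatean fuzzy numbers
#'
#' A Fermatean fuzzy number (FFN) is a pair (mu, nu) of membership and
#' non-membership degrees in \[0, 1\] constrained by mu^3 + nu^3 <= 1. The
#' constraint generalises the intuitionistic (mu + nu <= 1) and Pythagorean
#' (mu^2 + nu^2 <= 1) pairs; `q` selects the exponent so the same constructor
#' also validates intuitionistic pairs (`q = 1`) for the baseline operators.
#'
#' @param mu,nu Numeric vectors of membership / non-membership degrees,
#'   recycled to a common length.
#' @param mode `"strict"` aborts on any invalid pair; `"permissive"` keeps
#'   invalid pairs and marks them in a `valid` column.
#' @param q Constraint exponent: 3 for Fermatean pairs (default), 1 for
#'   intuitionistic pairs.
#' @param tol Validation tolerance on the power-sum constraint. The default
#'   absorbs decimal-literal rounding without admitting genuinely invalid
#'   pairs.
#'
#' @return A tibble with columns `mu`, `nu` and `valid` (logical).
#' @examples
#' ffn(0.9, 0.5)                      # valid: 0.729 + 0.125 <= 1
#' ffn(0.9, 0.8, mode = "permissive") # flagged: 0.729 + 0.512 > 1
#' @export
ffn <- function(mu, nu, mode = c("strict", "permissive"), q = 3, tol = 1e-9) {
  mode <- rlang::arg_match(mode)
  if (!is.numeric(mu) || !is.numeric(nu)) {
    rlang::abort("`mu` and `nu` must be numeric.", class = "fermadm_error")
  }
  n <- max(length(mu), length(nu))
  if (n == 0L) {
    rlang::abort("at least one (mu, nu) pair is required.",
                 class = "fermadm_error")
  }
  mu <- rep_len(mu, n)
  nu <- rep_len(nu, n)
  if (any(!is.finite(mu)) || any(!is.finite(nu))) {
    rlang::abort("`mu` and `nu` must be finite.", class = "fermadm_error")
  }
  out <- tibble::tibble(mu = as.double(mu), nu = as.double(nu))
  ff_validate(out, mode = mode, q = q, tol = tol)
}

#' Validate membership pairs against the power-sum constraint
#'
#' @param data A data frame with numeric columns `mu` and `nu`.
#' @inheritParams ffn
#' @return `data` as a tibble with a logical `valid` column appended (all
#'   `TRUE` in strict mode, which aborts instead of flagging).
#' @export
ff_validate <- function(data, mode = c("strict", "permissive"), q = 3,
                        tol = 1e-9) {
  mode <- rlang::arg_match(mode)
  check_pairs(data)
  data <- tibble::as_tibble(data)
  in_range <- data$mu >= 0 & data$mu <= 1 & data$nu >= 0 & data$nu <= 1
  power_ok <- data$mu^q + data$nu^q <= 1 + tol
  ok <- in_range & power_ok
  if (mode == "strict" && !all(ok)) {
    bad <- which(!ok)[1L]
    rlang::abort(
      sprintf(
        "invalid pair at position %d: (mu = %g, nu = %g) with mu^%d + nu^%d = %.6g %s",
        bad, data$mu[bad], data$nu[bad], q, q,
        data$mu[bad]^q + data$nu[bad]^q,
        if (in_range[bad]) "> 1" else "(component outside [0, 1])"
      ),
      class = "fermadm_invalid_ffn"
    )
  }
  data$valid <- ok
  data
}

check_pairs <- function(data, arg = rlang::caller_arg(data)) {
  if (!is.data.frame(data) || !all(c("mu", "nu") %in% names(data))) {
    rlang::abort(
      sprintf("`%s` must be a data frame with columns `mu` and `nu`.", arg),
      class = "fermadm_error"
    )
  }
  invisible(data)
}

#' Score, accuracy and indeterminacy of Fermatean fuzzy numbers
#'
#' The score g = mu^3 - nu^3 (in \[-1, 1\]) is the primary ranking key; the
#' accuracy H = mu^3 + nu^3 (in \[0, 1\]) breaks score ties; the indeterminacy
#' pi = (1 - mu^3 - nu^3)^(1/3) is the residual hesitation, so that
#' mu^3 + nu^3 + pi^3 = 1.
#'
#' @param data A data frame with columns `mu` and `nu`.
#' @param tol Tiny negative radicands within `tol` are clamped to zero before
#'   taking the cube root; larger ones signal an invalid pair and abort.
#' @return A numeric vector, one value per row.
#' @examples
#' ff_score(ffn(0.804, 0.496))  # ~0.397
#' ff_indeterminacy(ffn(0, 0))  # 1
#' @export
ff_score <- function(data) {
  check_pairs(data)
  data$mu^3 - data$nu^3
}

#' @rdname ff_score
#' @export
ff_accuracy <- function(data) {
  check_pairs(data)
  data$mu^3 + data$nu^3
}

#' @rdname ff_score
#' @export
ff_indeterminacy <- function(data, tol = 1e-9) {
  check_pairs(data)
  rad <- 1 - data$mu^3 - data$nu^3
  if (any(rad < -tol)) {
    bad <- which(rad < -tol)[1L]
    rlang::abort(
      sprintf("pair at position %d violates mu^3 + nu^3 <= 1 (excess %.3g).",
              bad, -rad[bad]),
      class = "fermadm_invalid_ffn"
    )
  }
  pmax(rad, 0)^(1 / 3)
}

#' Compare Fermatean fuzzy numbers
#'
#' Pairs are ordered by score; a score tie (within `tol`) falls through to the
#' accuracy; ties on both are `"equivalent"`. This is the total preorder used
#' for ranking and is deliberately distinct from [ff_leq()], the componentwise
#' partial order.
#'
#' @param f1,f2 Data frames with columns `mu` and `nu`; rows are compared
#'   positionally after recycling length-1 inputs.
#' @param tol Comparison tolerance for score/accuracy ties. Exact floating
#'   point equality is meaningless; the default treats differences below
#'   1e-12 as ties.
#' @return A character vector with elements `"first_greater"`,
#'   `"second_greater"` or `"equivalent"`.
#' @examples
#' ff_compare(ffn(0.8, 0.2), ffn(0.5, 0.5))  # first_greater
#' ff_compare(ffn(0.7, 0.7), ffn(0.5, 0.5))  # accuracy tie-break
#' @export
ff_compare <- function(f1, f2, tol = 1e-12) {
  check_pairs(f1)
  check_pairs(f2)
  n <- max(nrow(f1), nrow(f2))
  idx1 <- rep_len(seq_len(nrow(f1)), n)
  idx2 <- rep_len(seq_len(nrow(f2)), n)
  dg <- ff_score(f1)[idx1] - ff_score(f2)[idx2]
  dh <- ff_accuracy(f1)[idx1] - ff_accuracy(f2)[idx2]
  key <- ifelse(abs(dg) > tol, dg, ifelse(abs(dh) > tol, dh, 0))
  dplyr::case_when(
    key > 0 ~ "first_greater",
    key < 0 ~ "second_greater",
    .default = "equivalent"
  )
}

#' Componentwise partial order on Fermatean fuzzy numbers
#'
#' `ff_leq(f1, f2)` is `TRUE` where `mu1 <= mu2` and `nu1 <= nu2` — the
#' containment-style componentwise order, a partial order under which two
#' pairs may be incomparable. It must not be conflated with [ff_compare()],
#' the score/accuracy total preorder; the two orders disagree in general.
#' Equality of two FFNs (mutual containment) reduces to componentwise
#' equality of the pairs.
#'
#' @inheritParams ff_compare
#' @return A logical vector.
#' @export
ff_leq <- function(f1, f2) {
  check_pairs(f1)
  check_pairs(f2)
  n <- max(nrow(f1), nrow(f2))
  idx1 <- rep_len(seq_len(nrow(f1)), n)
  idx2 <- rep_len(seq_len(nrow(f2)), n)
  f1$mu[idx1] <= f2$mu[idx2] & f1$nu[idx1] <= f2$nu[idx2]
}

#' Complement of Fermatean fuzzy numbers
#'
#' Swaps membership and non-membership, an involution that negates the score.
#'
#' @param data A data frame with columns `mu` and `nu`.
#' @return A tibble with `mu` and `nu` swapped; other columns are preserved.
#' @examples
#' ff_complement(ffn(0.7, 0.4))
#' @export
ff_complement <- function(data) {
  check_pairs(data)
  data <- tibble::as_tibble(data)
  tmp <- data$mu
  data$mu <- data$nu
  data$nu <- tmp
  data
}

#' Validate a weight vector
#'
#' Weights (time weights over periods or attribute weights over criteria)
#' must lie in \[0, 1\] and sum to one. User-supplied CSVs often carry rounded
#' weights, so the sum is checked to a tolerance, and `normalize = TRUE`
#' rescales an almost-valid vector exactly.
#'
#' @param w A numeric vector of nonnegative weights.
#' @param normalize If `TRUE`, divide by `sum(w)` (which must be positive)
#'   before validating.
#' @param tol Tolerance on `|sum(w) - 1|`.
#' @param label Name used in error messages (e.g. `"time"` or `"attribute"`).
#' @return The validated (possibly rescaled) numeric weight vector.
#' @examples
#' ff_weights(c(0.2, 0.3, 0.5))
#' ff_weights(c(2, 3, 5), normalize = TRUE)
#' @export
ff_weights <- function(w, normalize = FALSE, tol = 1e-6, label = "weight") {
  if (!is.numeric(w) || length(w) == 0L || any(!is.finite(w))) {
    rlang::abort(sprintf("%s weights must be a non-empty finite numeric vector.",
                         label),
                 class = "fermadm_invalid_weights")
  }
  if (any(w < 0)) {
    rlang::abort(sprintf("%s weights must be nonnegative.", label),
                 class = "fermadm_invalid_weights")
  }
  if (normalize) {
    s <- sum(w)
    if (s <= 0) {
      rlang::abort(sprintf("%s weights sum to zero and cannot be normalized.",
                           label),
                   class = "fermadm_invalid_weights")
    }
    w <- w / s
  }
  if (abs(sum(w) - 1) > tol) {
    rlang::abort(
      sprintf("%s weights must sum to 1 (got %.8g); use `normalize = TRUE` for rounded inputs.",
              label, sum(w)),
      class = "fermadm_invalid_weights"
    )
  }
  if (any(w > 1 + tol)) {
    rlang::abort(sprintf("%s weights must lie in [0, 1].", label),
                 class = "fermadm_invalid_weights")
  }
  w
}
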