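#' Dynamic operational laws on Fermatean fuzzy numbers
#'
#' The algebra underlying the dynamic aggregation operators:
#' * `ff_add()` — the \eqn{\oplus} law,
#'   \eqn{(\sqrt[3]{\mu_1^3 + \mu_2^3 - \mu_1^3\mu_2^3},\ \nu_1\nu_2)};
#'   identity (0, 1), absorbing element (1, 0).
#' * `ff_mul()` — the dual \eqn{\otimes} law,
#'   \eqn{(\mu_1\mu_2,\ \sqrt[3]{\nu_1^3 + \nu_2^3 - \nu_1^3\nu_2^3})};
#'   identity (1, 0), absorbing element (0, 1).
#' * `ff_scale()` — the scalar multiple
#'   \eqn{(\sqrt[3]{1 - (1-\mu^3)^\epsilon},\ \nu^\epsilon)}.
#' * `ff_power()` — the dual power
#'   \eqn{(\mu^\epsilon,\ \sqrt[3]{1 - (1-\nu^3)^\epsilon})}.
#'
#' The two binary laws are De Morgan duals under [ff_complement()], and all
#' four are closed on the Fermatean constraint region.
#'
#' @param f1,f2,data Data frames with columns `mu` and `nu`; rows are combined
#'   positionally, length-1 inputs recycle.
#' @param eps A positive scalar exponent/coefficient.
#' @return A tibble of pairs (`mu`, `nu`).
#' @examples
#' ff_add(ffn(0.7, 0.6), ffn(0.8, 0.7))    # (0.8792, 0.42)
#' ff_scale(ffn(0.7, 0.6), 0.25)           # (0.4628, 0.8801)
#' @export
ff_add <- function(f1, f2) {
  check_pairs(f1)
  check_pairs(f2)
  n <- max(nrow(f1), nrow(f2))
  i1 <- rep_len(seq_len(nrow(f1)), n)
  i2 <- rep_len(seq_len(nrow(f2)), n)
  m1 <- f1$mu[i1]^3
  m2 <- f2$mu[i2]^3
  tibble::tibble(
    mu = clamp01(m1 + m2 - m1 * m2)^(1 / 3),
    nu = f1$nu[i1] * f2$nu[i2]
  )
}

#' @rdname ff_add
#' @export
ff_mul <- function(f1, f2) {
  ff_complement(ff_add(ff_complement(f1), ff_complement(f2)))
}

#' @rdname ff_add
#' @export
ff_scale <- function(data, eps) {
  check_pairs(data)
  check_eps(eps)
  tibble::tibble(
    mu = vapply(data$mu, function(m) one_minus_weighted_prod(m^3, eps), 0)^(1 / 3),
    nu = data$nu^eps
  )
}

#' @rdname ff_add
#' @export
ff_power <- function(data, eps) {
  ff_complement(ff_scale(ff_complement(data), eps))
}

check_eps <- function(eps) {
  if (!is.numeric(eps) || length(eps) != 1L || !is.finite(eps) || eps <= 0) {
    rlang::abort("`eps` must be a single positive number.",
                 class = "fermadm_error")
  }
  invisible(eps)
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

# Weighted product prod(x_i^w_i) in log space. Conventions: a zero weight
# drops its factor (0^0 := 1); any remaining exact zero factor short-circuits
# the product to 0; exact ones contribute nothing. Log-space accumulation
# avoids underflow for long series without changing results beyond ~1e-15.
weighted_prod <- function(x, w) {
  keep <- w != 0
  x <- x[keep]
  w <- w[keep]
  if (length(x) == 0L) return(1)
  if (any(x == 0)) return(0)
  exp(sum(w * log(x)))
}

# 1 - prod((1 - x_i)^w_i) via log1p/expm1, so the complement survives when
# every x_i is tiny (plain pow would collapse 1 - x to 1 and idempotency
# would degrade near the mu = 0 boundary). Same zero-weight and absorbing
# conventions as weighted_prod.
one_minus_weighted_prod <- function(x, w) {
  keep <- w != 0
  x <- x[keep]
  w <- w[keep]
  if (length(x) == 0L) return(0)
  if (any(x == 1)) return(1)
  clamp01(-expm1(sum(w * log1p(-x))))
}

# Shared closed-form kernel for every weighted operator in the package.
# q = 3 gives the Fermatean operators, q = 1 the intuitionistic baselines;
# form "averaging" is prod-complement on mu, "geometric" its dual on nu.
agg_kernel <- function(mu, nu, w, q, form = c("averaging", "geometric")) {
  form <- rlang::arg_match(form)
  if (length(mu) != length(w)) {
    rlang::abort(
      sprintf("got %d values but %d weights.", length(mu), length(w)),
      class = "fermadm_length_mismatch"
    )
  }
  if (form == "averaging") {
    tibble::tibble(
      mu = one_minus_weighted_prod(mu^q, w)^(1 / q),
      nu = weighted_prod(nu, w)
    )
  } else {
    tibble::tibble(
      mu = weighted_prod(mu, w),
      nu = one_minus_weighted_prod(nu^q, w)^(1 / q)
    )
  }
}

#' Dynamic weighted aggregation of a Fermatean fuzzy time series
#'
#' Aggregates FFNs collected at `p` time periods into a single FFN using the
#' closed forms
#' \deqn{FFDyWA = \left(\sqrt[3]{1 - \prod_k (1-\mu_k^3)^{\epsilon_k}},\
#'   \prod_k \nu_k^{\epsilon_k}\right)}
#' \deqn{FFDyWG = \left(\prod_k \mu_k^{\epsilon_k},\
#'   \sqrt[3]{1 - \prod_k (1-\nu_k^3)^{\epsilon_k}}\right)}
#' where \eqn{\epsilon} is the time-weight vector. Both operators are
#' idempotent, bounded by the componentwise min/max envelope, monotone in the
#' componentwise order, closed on the Fermatean region, and mutual duals
#' under the complement. The averaging form always dominates the geometric
#' form (weighted power-mean inequality). Products are accumulated in log
#' space, so long series do not underflow.
#'
#' @param series A data frame with columns `mu` and `nu`, one row per period,
#'   in period order.
#' @param eps Time weights, one per row of `series`; validated with
#'   [ff_weights()].
#' @param normalize Passed to [ff_weights()] to rescale rounded weights.
#' @return A one-row tibble (`mu`, `nu`).
#' @examples
#' # three assessments of one item over three periods
#' ffdywa(ffn(c(0.7, 0.8, 0.9), c(0.6, 0.7, 0.5)), c(0.25, 0.3, 0.45))
#' ffdywg(ffn(c(0.9, 0.8, 0.7, 0.6), c(0.4, 0.5, 0.3, 0.5)),
#'        c(0.25, 0.47, 0.13, 0.15))
#' @export
ffdywa <- function(series, eps, normalize = FALSE) {
  check_pairs(series)
  eps <- ff_weights(eps, normalize = normalize, label = "time")
  agg_kernel(series$mu, series$nu, eps, q = 3, form = "averaging")
}

#' @rdname ffdywa
#' @export
ffdywg <- function(series, eps, normalize = FALSE) {
  check_pairs(series)
  eps <- ff_weights(eps, normalize = normalize, label = "time")
  agg_kernel(series$mu, series$nu, eps, q = 3, form = "geometric")
}

#' Weighted aggregation across attributes
#'
#' The per-period (time-free) operators used in the second stage of the
#' ranking pipeline. `ffwa()` and `ffwg()` are the power forms — numerically
#' identical to [ffdywa()] / [ffdywg()] with the weights relabelled as
#' attribute weights (one shared kernel). `ffwa_arithmetic()` is the
#' componentwise weighted arithmetic mean
#' \eqn{(\sum_j \omega_j \mu_j, \sum_j \omega_j \nu_j)}, a distinct operator
#' that circulates under the same FFWA name; it is exported for completeness
#' but the pipeline uses the power form, which is the one whose outputs the
#' worked case study reproduces. Convexity of the constraint region makes the
#' arithmetic form closed as well.
#'
#' @param row A data frame with columns `mu` and `nu`, one row per attribute.
#' @param omega Attribute weights, one per row; validated with [ff_weights()].
#' @param normalize Passed to [ff_weights()].
#' @return A one-row tibble (`mu`, `nu`).
#' @examples
#' ffwa(ffn(c(0.7, 0.8, 0.9), c(0.6, 0.7, 0.5)), c(0.25, 0.3, 0.45))
#' ffwa_arithmetic(ffn(c(0.7, 0.8, 0.9), c(0.6, 0.7, 0.5)), c(0.25, 0.3, 0.45))
#' @export
ffwa <- function(row, omega, normalize = FALSE) {
  check_pairs(row)
  omega <- ff_weights(omega, normalize = normalize, label = "attribute")
  agg_kernel(row$mu, row$nu, omega, q = 3, form = "averaging")
}

#' @rdname ffwa
#' @export
ffwg <- function(row, omega, normalize = FALSE) {
  check_pairs(row)
  omega <- ff_weights(omega, normalize = normalize, label = "attribute")
  agg_kernel(row$mu, row$nu, omega, q = 3, form = "geometric")
}

#' @rdname ffwa
#' @export
ffwa_arithmetic <- function(row, omega, normalize = FALSE) {
  check_pairs(row)
  omega <- ff_weights(omega, normalize = normalize, label = "attribute")
  if (nrow(row) != length(omega)) {
    rlang::abort(
      sprintf("got %d values but %d weights.", nrow(row), length(omega)),
      class = "fermadm_length_mismatch"
    )
  }
  tibble::tibble(mu = sum(omega * row$mu), nu = sum(omega * row$nu))
}

#' Intuitionistic fuzzy dynamic baselines
#'
#' The exponent-1 counterparts of [ffdywa()] / [ffdywg()], used to compare the
#' Fermatean pipeline with the classical intuitionistic dynamic operators:
#' \deqn{IFDWA = \left(1 - \prod_k (1-\mu_k)^{\epsilon_k},\
#'   \prod_k \nu_k^{\epsilon_k}\right), \quad
#'   IFDWG = \left(\prod_k \mu_k^{\epsilon_k},\
#'   1 - \prod_k (1-\nu_k)^{\epsilon_k}\right)}
#' with score `if_score()` = mu - nu. Intuitionistic pairs require
#' mu + nu <= 1; Fermatean data generally violate that, so the baselines are
#' typically run in permissive mode (see [ff_decide()]), which is the point
#' of the comparison: the Fermatean constraint admits evaluations the
#' intuitionistic one cannot.
#'
#' @inheritParams ffdywa
#' @param data A data frame with columns `mu` and `nu`.
#' @return A one-row tibble for the aggregators; a numeric vector for
#'   `if_score()`.
#' @examples
#' ifdwa(ffn(c(0.9, 0.7, 0.9), c(0.6, 0.5, 0.5), mode = "permissive"),
#'       c(0.2, 0.3, 0.5))
#' if_score(data.frame(mu = 0.793, nu = 0.496))
#' @export
ifdwa <- function(series, eps, normalize = FALSE) {
  check_pairs(series)
  eps <- ff_weights(eps, normalize = normalize, label = "time")
  agg_kernel(series$mu, series$nu, eps, q = 1, form = "averaging")
}

#' @rdname ifdwa
#' @export
ifdwg <- function(series, eps, normalize = FALSE) {
  check_pairs(series)
  eps <- ff_weights(eps, normalize = normalize, label = "time")
  agg_kernel(series$mu, series$nu, eps, q = 1, form = "geometric")
}

#' @rdname ifdwa
#' @export
if_score <- function(data) {
  check_pairs(data)
  data$mu - data$nu
}
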