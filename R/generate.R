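#' Generate a random decision tensor
#'
#' Draws a reproducible m x n x p tensor of valid pairs under the exponent-q
#' constraint: mu is uniform on \[0, 1\] and, given mu, nu is uniform on
#' \[0, (1 - mu^q)^(1/q)\] — the full admissible interval, so the sampler
#' covers the whole constraint region including near-boundary pairs. The
#' caller's RNG state is saved and restored, so generation never disturbs
#' global random state.
#'
#' @param m,n,p Numbers of alternatives, attributes and periods.
#' @param seed Mandatory integer seed; identical arguments give identical
#'   tensors.
#' @param q Constraint exponent (3 Fermatean, 1 intuitionistic).
#' @param time_weights,attribute_weights Optional weights to attach; by
#'   default uniform weights `1/p` and `1/n` are attached.
#' @return An [ff_tensor()].
#' @examples
#' ff_simulate_tensor(4, 5, 3, seed = 1)
#' @export
ff_simulate_tensor <- function(m, n, p, seed, q = 3,
                               time_weights = rep(1 / p, p),
                               attribute_weights = rep(1 / n, n)) {
  stopifnot(m >= 1, n >= 1, p >= 1)
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L ||
      !is.finite(seed)) {
    rlang::abort("`seed` is mandatory and must be a single integer.",
                 class = "fermadm_error")
  }
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))

  cells <- tidyr::expand_grid(
    period = paste0("t", seq_len(p)),
    alternative = paste0("A", seq_len(m)),
    attribute = paste0("C", seq_len(n))
  )
  mu <- stats::runif(nrow(cells))
  nu <- stats::runif(nrow(cells)) * (1 - mu^q)^(1 / q)
  cells$mu <- mu
  cells$nu <- nu
  ff_tensor(cells, time_weights = time_weights,
            attribute_weights = attribute_weights, mode = "strict", q = q)
}
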