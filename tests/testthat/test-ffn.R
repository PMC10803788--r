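test_that("construction validates the cubic constraint in both modes", {
  ok <- ffn(0.9, 0.5)
  expect_true(ok$valid)
  expect_true(all(ffn(c(1, 0, 0.5), c(0, 1, 0.5))$valid))

  expect_error(ffn(0.9, 0.8), class = "fermadm_invalid_ffn")
  expect_error(ffn(0.9, 0.8), "0.9")
  expect_error(ffn(-0.1, 0.5), class = "fermadm_invalid_ffn")
  expect_error(ffn(0.5, 1.2), class = "fermadm_invalid_ffn")
  expect_error(ffn(NA_real_, 0.5), class = "fermadm_error")

  flagged <- ffn(c(0.9, 0.7), c(0.8, 0.2), mode = "permissive")
  expect_equal(flagged$valid, c(FALSE, TRUE))

  # validation tolerance absorbs decimal-literal rounding at the boundary
  expect_true(ffn(1, 1e-10)$valid)
  # exponent-1 (intuitionistic) validation rejects what q = 3 accepts
  expect_error(ffn(0.9, 0.5, q = 1), class = "fermadm_invalid_ffn")
})

test_that("score, accuracy and indeterminacy follow the cubic definitions", {
  expect_equal(ff_score(ffn(0.804, 0.496)), 0.804^3 - 0.496^3)
  expect_near(ff_score(ffn(0.804, 0.496)), 0.397)
  expect_equal(ff_score(ffn(c(0.3, 0.7), c(0.3, 0.7), mode = "permissive")),
               c(0, 0))
  expect_equal(ff_score(ffn(1, 0)), 1)

  expect_equal(ff_accuracy(ffn(1, 0)), 1)
  expect_equal(ff_accuracy(ffn(0, 0)), 0)
  expect_equal(ff_accuracy(ffn(0.7, 0.6)), 0.559)

  expect_equal(ff_indeterminacy(ffn(0, 0)), 1)
  expect_equal(ff_indeterminacy(ffn(1, 0)), 0)
  expect_equal(ff_indeterminacy(ffn(0.7, 0.6)), 0.441^(1 / 3))
  expect_error(ff_indeterminacy(data.frame(mu = 0.9, nu = 0.8)),
               class = "fermadm_invalid_ffn")
})

test_that("mu^3 + nu^3 + pi^3 = 1 and ranges hold over the sampled region", {
  f <- rand_pairs(1000, seed = 42)
  expect_true(all(abs(f$mu^3 + f$nu^3 + ff_indeterminacy(f)^3 - 1) < 1e-12))
  g <- ff_score(f)
  h <- ff_accuracy(f)
  expect_true(all(g >= -1 & g <= 1))
  expect_true(all(h >= 0 & h <= 1))
})

test_that("comparison orders by score then accuracy, with explicit ties", {
  expect_equal(ff_compare(ffn(0.8, 0.2), ffn(0.5, 0.5)), "first_greater")
  expect_equal(ff_compare(ffn(0.5, 0.5), ffn(0.8, 0.2)), "second_greater")
  # equal scores (both 0), accuracy breaks the tie
  expect_equal(ff_compare(ffn(0.7, 0.7, mode = "permissive"), ffn(0.5, 0.5)),
               "first_greater")
  f <- ffn(0.6, 0.3)
  expect_equal(ff_compare(f, f), "equivalent")
})

test_that("comparison is a total preorder on sampled triples", {
  f <- rand_pairs(300, seed = 7)
  i <- sample(300, 200, replace = TRUE)
  j <- sample(300, 200, replace = TRUE)
  k <- sample(300, 200, replace = TRUE)
  ab <- ff_compare(f[i, ], f[j, ])
  ba <- ff_compare(f[j, ], f[i, ])
  # antisymmetry up to equivalence
  expect_true(all((ab == "first_greater") == (ba == "second_greater")))
  expect_true(all((ab == "equivalent") == (ba == "equivalent")))
  # transitivity: a >= b and b >= c imply a >= c
  bc <- ff_compare(f[j, ], f[k, ])
  ac <- ff_compare(f[i, ], f[k, ])
  premise <- ab != "second_greater" & bc != "second_greater"
  expect_true(all(ac[premise] != "second_greater"))
})

test_that("complement is an involution that negates the score", {
  expect_equal(ff_complement(ffn(0.7, 0.4)),
               tibble::tibble(mu = 0.4, nu = 0.7, valid = TRUE))
  f <- rand_pairs(500, seed = 3)
  expect_equal(ff_complement(ff_complement(f)), f)
  expect_equal(ff_score(ff_complement(f)), -ff_score(f), tolerance = 1e-12)
  expect_equal(ff_complement(ffn(0.5, 0.5))$mu, 0.5)
})

test_that("the componentwise partial order is distinct from the ranking order", {
  expect_true(ff_leq(ffn(0.5, 0.3), ffn(0.6, 0.4)))
  expect_false(ff_leq(ffn(0.5, 0.5), ffn(0.6, 0.4)))
  # ranked higher yet not componentwise-below: the two orders disagree
  expect_equal(ff_compare(ffn(0.6, 0.4), ffn(0.5, 0.5)), "first_greater")
  expect_false(ff_leq(ffn(0.5, 0.5), ffn(0.6, 0.4)))
})

test_that("weight validation enforces the simplex and can normalize", {
  expect_equal(ff_weights(c(0.2, 0.3, 0.5)), c(0.2, 0.3, 0.5))
  expect_equal(ff_weights(c(2, 3, 5), normalize = TRUE), c(0.2, 0.3, 0.5))
  expect_error(ff_weights(c(0.2, 0.3)), class = "fermadm_invalid_weights")
  expect_error(ff_weights(c(-0.2, 1.2)), class = "fermadm_invalid_weights")
  expect_error(ff_weights(numeric()), class = "fermadm_invalid_weights")
  # rounded CSV weights pass within the documented tolerance
  expect_silent(ff_weights(c(0.333333, 0.333333, 0.333334)))
})
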