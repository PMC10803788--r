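test_that("dynamic averaging reproduces the worked three- and four-period cases", {
  # three periods, weights (0.25, 0.3, 0.45)
  ex1 <- ffdywa(ffn(c(0.7, 0.8, 0.9), c(0.6, 0.7, 0.5)), c(0.25, 0.3, 0.45))
  expect_near(ex1$mu, 0.841)
  expect_near(ex1$nu, 0.578)
  # the intermediate weighted product over (1 - mu^3)
  expect_near(prod((1 - c(0.7, 0.8, 0.9)^3)^c(0.25, 0.3, 0.45)), 0.403)

  # four periods, weights (0.2, 0.4, 0.3, 0.1)
  ex2 <- ffdywa(ffn(c(0.8, 0.6, 0.6, 0.9), c(0.7, 0.7, 0.8, 0.4)),
                c(0.2, 0.4, 0.3, 0.1))
  expect_near(ex2$mu, 0.710)
  expect_near(ex2$nu, 0.688)
})

test_that("dynamic geometric reproduces the worked cases (formula-consistent)", {
  ex4 <- ffdywg(ffn(c(0.9, 0.8, 0.7, 0.6), c(0.4, 0.5, 0.3, 0.5)),
                c(0.25, 0.47, 0.13, 0.15))
  expect_near(ex4$mu, 0.775)
  expect_near(ex4$nu, 0.461)
  expect_near(prod((1 - c(0.4, 0.5, 0.3, 0.5)^3)^c(0.25, 0.47, 0.13, 0.15)),
              0.902)

  # three-period case: the membership component is a regression value; the
  # non-membership is asserted against the closed form itself, because the
  # circulating 0.881 print contradicts closure (0.781^3 + 0.881^3 > 1)
  ex3 <- ffdywg(ffn(c(0.9, 0.8, 0.7), c(0.3, 0.6, 0.8)), c(0.25, 0.35, 0.4))
  expect_near(ex3$mu, 0.781)
  nu_expected <- oracle_dywg(c(0.9, 0.8, 0.7), c(0.3, 0.6, 0.8),
                             c(0.25, 0.35, 0.4))[["nu"]]
  expect_equal(ex3$nu, nu_expected, tolerance = 1e-12)
  expect_near(ex3$nu, 0.6807)
  expect_lt(ex3$mu^3 + ex3$nu^3, 1 + 1e-12)
})

test_that("aggregates are closed, idempotent and bounded on random series", {
  set.seed(101)
  for (trial in 1:1000) {
    p <- sample(1:6, 1)
    f <- rand_pairs(p)
    w <- rand_weights(p)
    a <- ffdywa(f, w)
    g <- ffdywg(f, w)
    if (a$mu^3 + a$nu^3 > 1 + 1e-12 || g$mu^3 + g$nu^3 > 1 + 1e-12) {
      fail(sprintf("closure violated at trial %d", trial))
    }
    if (a$mu < min(f$mu) - 1e-12 || a$mu > max(f$mu) + 1e-12 ||
        a$nu < min(f$nu) - 1e-12 || a$nu > max(f$nu) + 1e-12 ||
        g$mu < min(f$mu) - 1e-12 || g$mu > max(f$mu) + 1e-12 ||
        g$nu < min(f$nu) - 1e-12 || g$nu > max(f$nu) + 1e-12) {
      fail(sprintf("boundedness violated at trial %d", trial))
    }
  }
  succeed()

  # idempotency: p identical inputs return the input
  set.seed(202)
  for (trial in 1:50) {
    f1 <- rand_pairs(1)
    p <- sample(2:8, 1)
    rep_f <- f1[rep(1, p), ]
    w <- rand_weights(p)
    expect_equal(unlist(ffdywa(rep_f, w)), c(mu = f1$mu, nu = f1$nu),
                 tolerance = 1e-12)
    expect_equal(unlist(ffdywg(rep_f, w)), c(mu = f1$mu, nu = f1$nu),
                 tolerance = 1e-12)
  }
})

test_that("aggregates are monotone in the componentwise dominance order", {
  set.seed(303)
  for (trial in 1:200) {
    p <- sample(2:5, 1)
    f <- rand_pairs(p)
    w <- rand_weights(p)
    # raise memberships, lower non-memberships
    g <- f
    g$mu <- f$mu + runif(p) * (1 - f$mu) * 0.5
    g$nu <- f$nu * runif(p)
    g$nu <- pmin(g$nu, (1 - g$mu^3)^(1 / 3))
    af <- ffdywa(f, w); ag <- ffdywa(g, w)
    gf <- ffdywg(f, w); gg <- ffdywg(g, w)
    if (ag$mu < af$mu - 1e-12 || ag$nu > af$nu + 1e-12 ||
        gg$mu < gf$mu - 1e-12 || gg$nu > gf$nu + 1e-12) {
      fail(sprintf("monotonicity violated at trial %d", trial))
    }
  }
  succeed()
})

test_that("averaging and geometric are complement duals and ordered", {
  set.seed(404)
  for (trial in 1:200) {
    p <- sample(1:6, 1)
    f <- rand_pairs(p)
    w <- rand_weights(p)
    # duality under complement
    dual <- ff_complement(ffdywa(ff_complement(f), w))
    expect_equal(ffdywg(f, w), dual[, c("mu", "nu")], tolerance = 1e-12)
    # weighted power-mean inequality: averaging dominates geometric
    a <- ffdywa(f, w)
    g <- ffdywg(f, w)
    expect_gte(a$mu, g$mu - 1e-12)
    expect_lte(a$nu, g$nu + 1e-12)
  }
})

test_that("a single period with unit weight is the identity", {
  f <- rand_pairs(1, seed = 9)
  expect_equal(ffdywa(f, 1), f[, c("mu", "nu")], tolerance = 1e-15)
  expect_equal(ffdywg(f, 1), f[, c("mu", "nu")], tolerance = 1e-15)
})

test_that("zero weights drop periods and zero/one components behave as limits", {
  f <- ffn(c(0.7, 0.8), c(0.6, 0.2))
  # weight (1, 0) ignores the second period entirely
  expect_equal(ffdywa(f, c(1, 0)), f[1, c("mu", "nu")], tolerance = 1e-15)
  # a (1, 0) entry with positive weight saturates the averaging membership
  sat <- ffdywa(ffn(c(1, 0.5), c(0, 0.5)), c(0.5, 0.5))
  expect_equal(sat$mu, 1)
  expect_equal(sat$nu, 0)
  # a (0, 1) entry with positive weight annihilates the geometric membership
  ann <- ffdywg(ffn(c(0, 0.5), c(1, 0.5)), c(0.5, 0.5))
  expect_equal(ann$mu, 0)
  expect_equal(ann$nu, 1)
})

test_that("log-space kernel agrees with the naive direct-product oracle", {
  set.seed(505)
  for (trial in 1:1000) {
    p <- sample(1:40, 1)
    f <- rand_pairs(p)
    w <- rand_weights(p)
    expect_near(unlist(ffdywa(f, w)), oracle_dywa(f$mu, f$nu, w),
                tol = 1e-12)
    expect_near(unlist(ffdywg(f, w)), oracle_dywg(f$mu, f$nu, w),
                tol = 1e-12)
  }
})

test_that("log-space kernel matches a 50-digit high-precision oracle", {
  set.seed(606)
  instances <- purrr::map(1:20, function(i) {
    p <- sample(2:30, 1)
    f <- rand_pairs(p)
    w <- rand_weights(p)
    list(mu = format(f$mu, digits = 17), nu = format(f$nu, digits = 17),
         w = format(w, digits = 17), q = 3)
  })
  infile <- tempfile(fileext = ".json")
  outfile <- tempfile(fileext = ".json")
  jsonlite::write_json(instances, infile, auto_unbox = TRUE)
  pysrc <- tempfile(fileext = ".py")
  writeLines(c(
    "import sys, json",
    "from mpmath import mp, mpf, power",
    "mp.dps = 50",
    "insts = json.load(open(sys.argv[1]))",
    "out = []",
    "for inst in insts:",
    "    mu = [mpf(s) for s in inst['mu']]",
    "    nu = [mpf(s) for s in inst['nu']]",
    "    w = [mpf(s) for s in inst['w']]",
    "    q = inst['q']",
    "    pm = mpf(1); pn = mpf(1); qm = mpf(1); qn = mpf(1)",
    "    for m, n, wk in zip(mu, nu, w):",
    "        pm *= power(1 - power(m, q), wk)",
    "        pn *= power(n, wk)",
    "        qm *= power(m, wk)",
    "        qn *= power(1 - power(n, q), wk)",
    "    out.append({'wa': [float(power(1 - pm, mpf(1) / q)), float(pn)],",
    "                'wg': [float(qm), float(power(1 - qn, mpf(1) / q))]})",
    "json.dump(out, open(sys.argv[2], 'w'))"
  ), pysrc)
  status <- system2("python", c(pysrc, infile, outfile))
  expect_identical(status, 0L)
  ref <- jsonlite::fromJSON(outfile, simplifyDataFrame = FALSE)
  for (i in seq_along(instances)) {
    f <- tibble::tibble(mu = as.numeric(instances[[i]]$mu),
                        nu = as.numeric(instances[[i]]$nu))
    w <- as.numeric(instances[[i]]$w)
    expect_near(unlist(ffdywa(f, w)), unlist(ref[[i]]$wa), tol = 1e-12)
    expect_near(unlist(ffdywg(f, w)), unlist(ref[[i]]$wg), tol = 1e-12)
  }
})

test_that("length mismatches and bad weights are rejected", {
  f <- rand_pairs(3, seed = 1)
  expect_error(ffdywa(f, c(0.5, 0.5)), class = "fermadm_length_mismatch")
  expect_error(ffdywg(f, c(0.2, 0.2, 0.2)), class = "fermadm_invalid_weights")
  expect_equal(ffdywa(f, c(20, 30, 50), normalize = TRUE),
               ffdywa(f, c(0.2, 0.3, 0.5)))
})
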