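# Quotients of transmission rate to fluctuation level: closed forms,
# symmetry, limits, bounds, critical parameters, sampled curves.

VARIANTS <- c("shannon", "taylor10", "unimodal", "unimodal_root")

test_that("q_sigma matches reference values and the rate/sigma ratio", {
  expect_equal(q_sigma(1, 0.5), 2)
  expect_equal(q_sigma(0.5, 0.25), 2 * shannon_h(0.25), tolerance = 1e-14)
  expect_equal(q_sigma(0.5, 0.2), 1.6037487377513792, tolerance = 1e-12)
  m <- markov_params(0.2, 0.3)
  expect_equal(q_sigma(0.5, 0.2), markov_itr(m) / markov_sigma(m),
               tolerance = 1e-12)
})

test_that("q_variance matches reference values and the rate/variance ratio", {
  expect_equal(q_variance(1, 0.5), 4)
  expect_equal(q_variance(0.5, 0.2, "unimodal"), 3, tolerance = 1e-14)
  expect_equal(q_variance(0.5, 0.2), 3.2736384026028936, tolerance = 1e-12)
  m <- markov_params(0.2, 0.3)
  expect_equal(q_variance(0.5, 0.2), markov_itr(m) / markov_variance(m),
               tolerance = 1e-12)
})

test_that("quotients are consistent with the source and with each other", {
  src <- draw_sources(100, seed = 3)
  for (i in seq_len(100)) {
    s <- src$s[i]; p <- src$p10[i]
    m <- markov_params(p, src$p01[i])
    expect_equal(q_sigma(s, p) * markov_sigma(m), markov_itr(m),
                 tolerance = 1e-12)
    expect_equal(q_variance(s, p) * markov_variance(m), markov_itr(m),
                 tolerance = 1e-12)
    expect_equal(q_variance(s, p) * markov_sigma(m), q_sigma(s, p),
                 tolerance = 1e-12)
  }
})

test_that("both quotients are symmetric about p10 = s/2 for every variant", {
  src <- draw_sources(200, seed = 5)
  for (v in VARIANTS) {
    qs <- mapply(function(s, p) q_sigma(s, p, v), src$s, src$p10)
    qs_ref <- mapply(function(s, p) q_sigma(s, s - p, v), src$s, src$p10)
    expect_equal(qs, qs_ref, tolerance = 1e-9, info = v)
    qv <- mapply(function(s, p) q_variance(s, p, v), src$s, src$p10)
    qv_ref <- mapply(function(s, p) q_variance(s, s - p, v), src$s, src$p10)
    expect_equal(qv, qv_ref, tolerance = 1e-9, info = v)
  }
})

test_that("the center value 2 f(s/2) is the maximum of q_sigma", {
  expect_equal(q_sigma_center(1, "shannon"), 2)
  expect_equal(q_sigma_center(0.5, "shannon"), 1.6225562489182657,
               tolerance = 1e-12)
  expect_equal(q_sigma_center(1, "unimodal"), 2)
  for (s in c(0.3, 0.8, 1.2, 1.7)) {
    expect_equal(q_sigma_center(s), q_sigma(s, s / 2), tolerance = 1e-14)
    grid <- quotient_curve(s, kind = "sigma", n_points = 201)
    expect_lte(max(grid$value), q_sigma_center(s) + 1e-12)
  }
})

test_that("q_sigma boundary limits: collapse for s < 1, finite floor for s > 1", {
  expect_equal(q_sigma_boundary_limit(0.5), 0)
  expect_equal(q_sigma_boundary_limit(1.5), sqrt(2), tolerance = 1e-12)
  expect_equal(q_sigma_boundary_limit(1.5, "unimodal"), sqrt(2),
               tolerance = 1e-12)
  # closed forms agree with near-boundary evaluation
  for (v in c("shannon", "unimodal")) {
    expect_equal(q_sigma(1.5, 1 - 1e-8, v), q_sigma_boundary_limit(1.5, v),
                 tolerance = 1e-6, info = v)
    expect_equal(q_sigma(1.5, 0.5 + 1e-8, v), q_sigma_boundary_limit(1.5, v),
                 tolerance = 1e-3, info = v)
  }
  # for s < 1 the quotient decreases to 0 monotonically near the
  # boundary; the collapse is logarithmically slow (~ sqrt(p) log p)
  eps <- 10^-(2:8)
  vals <- q_sigma(0.5, eps)
  expect_true(all(diff(vals) < 0))
  expect_lt(vals[length(vals)], 0.01)
  expect_error(q_sigma_boundary_limit(1), "Bernoulli")
})

test_that("for 1 < s < 2 the quotient is pinched between limit and center", {
  b <- q_sigma_bounds(1.5)
  expect_equal(unname(b), c(sqrt(2), 1.6225562489182657), tolerance = 1e-12)
  b9 <- q_sigma_bounds(1.9)
  expect_equal(unname(b9), c(0.4943647627749308, 0.5727939142319123),
               tolerance = 1e-12)
  expect_error(q_sigma_bounds(0.5), "1 < s < 2")
  set.seed(9)
  for (s in runif(50, 1 + 1e-3, 2 - 1e-3)) {
    b <- q_sigma_bounds(s)
    v <- quotient_curve(s, kind = "sigma", n_points = 101)$value
    expect_true(all(v >= b["lower"] - 1e-9), info = sprintf("s = %g", s))
    expect_true(all(v <= b["upper"] + 1e-9), info = sprintf("s = %g", s))
  }
})

test_that("q_variance boundary behaviour: blowup for s < 1, finite for s > 1", {
  expect_identical(q_variance_boundary_limit(0.5), Inf)
  expect_equal(q_variance_boundary_limit(1.5), 3, tolerance = 1e-12)
  expect_equal(q_variance_boundary_limit(1.5, "unimodal"), 3,
               tolerance = 1e-12)
  expect_equal(q_variance(1.5, 1 - 1e-8), 3, tolerance = 1e-6)
  # unbounded increase towards the boundary for s < 1; the divergence is
  # logarithmic, ~ -s log2(p)
  eps <- 10^-(2:8)
  vals <- q_variance(0.5, eps)
  expect_true(all(diff(vals) > 0))
  expect_gt(vals[length(vals)], 10)
  # the unimodal variant has no blowup: its curve is constant
  expect_equal(q_variance_boundary_limit(0.5, "unimodal"), 4 * 0.5 * 1.5,
               tolerance = 1e-14)
  expect_error(q_variance_boundary_limit(1), "Bernoulli")
})

test_that("s0 = 4/3 is where the Q_V center value crosses the boundary limit", {
  res <- critical_s0(1e-10)
  expect_s3_class(res, "critical_result")
  expect_equal(res$value, 4 / 3, tolerance = 1e-9)
  expect_lt(res$residual, 1e-10)
  expect_gte(res$value, res$bracket[1])
  expect_lte(res$value, res$bracket[2])
  # below s0 the center value 4H(s/2) sits below the boundary limit
  # s H(s-1)/(s-1); above s0, above it
  for (s in c(res$value - 0.05, res$value - 0.01)) {
    expect_lt(4 * shannon_h(s / 2), q_variance_boundary_limit(s))
  }
  for (s in c(res$value + 0.01, res$value + 0.05)) {
    expect_gt(4 * shannon_h(s / 2), q_variance_boundary_limit(s))
  }
  expect_error(critical_s0(0), "tolerance")
})

test_that("the local curvature of the Q_V center flips near s = 1.431", {
  # Q''(s/2) = 2s (H(y)/y)''|_{y=s/2}; the second derivative of H(y)/y
  # vanishes at y = 0.71533..., i.e. s = 1.43066 (oracle value)
  curv <- function(s, h = 1e-4) {
    (q_variance(s, s / 2 + h) - 2 * q_variance(s, s / 2) +
       q_variance(s, s / 2 - h)) / h^2
  }
  expect_gt(curv(1.35), 0)   # center still a local minimum
  expect_gt(curv(1.42), 0)
  expect_lt(curv(1.44), 0)   # center now a local maximum
  expect_lt(curv(1.5), 0)
  expect_equal(curv(1.43066372591832), 0, tolerance = 1e-2)
})

test_that("the sigma < ITR regime extends to s* of about 1.72", {
  res <- sigma_itr_threshold(1e-9)
  expect_gte(res$value, 1.7)
  expect_equal(res$value, 1.7235252269268052, tolerance = 1e-8)
  expect_lt(abs(shannon_h(res$value - 1) / sqrt(res$value - 1) - 1), 1e-9)
  # below s* the case-B infimum keeps the whole curve above 1
  v <- quotient_curve(1.5, kind = "sigma", n_points = 1001)$value
  expect_gt(min(v), 1)
  expect_equal(min(v), q_sigma_boundary_limit(1.5), tolerance = 1e-2)
})

test_that("quotient_curve satisfies its grid invariants", {
  for (kind in c("sigma", "variance")) {
    qc <- quotient_curve(1.3, kind = kind, n_points = 200)
    expect_equal(nrow(qc), 201)  # forced odd: midpoint on the grid
    expect_true(all(diff(qc$p10) > 0))
    bounds <- c(1.3 - 1, 1)
    expect_true(all(qc$p10 > bounds[1] & qc$p10 < bounds[2]))
    expect_true(all(is.finite(qc$value) & qc$value >= 0))
    # mirrored grid points carry equal values
    expect_equal(qc$value, rev(qc$value), tolerance = 1e-9)
    expect_equal(qc$p10[101], 1.3 / 2, tolerance = 1e-12)
  }
  expect_error(quotient_curve(0.5, n_points = 2), "at least 3")
  expect_error(quotient_curve(0.5, eps = 0.3), "eps")
})

test_that("extremum counts reproduce the regime structure", {
  # single maximum at the symmetry point for persistent sources
  for (s in c(0.3, 0.5, 0.8)) {
    qc <- quotient_curve(s, kind = "sigma", n_points = 1001)
    expect_identical(count_local_extrema(qc), 1L)
  }
  # Q_V develops three interior extrema (boundary-adjacent maxima around
  # a central minimum) for s roughly in (1.06, 1.43); beyond the
  # curvature flip the curve is unimodal again
  for (s in c(1.2, 1.3, 1.4)) {
    qc <- quotient_curve(s, kind = "variance", n_points = 1001)
    expect_identical(count_local_extrema(qc), 3L)
  }
  for (s in c(1.5, 1.8)) {
    qc <- quotient_curve(s, kind = "variance", n_points = 1001)
    expect_identical(count_local_extrema(qc), 1L)
  }
  # the unimodal-variant Q_V curve is constant: no strict extrema
  qc <- quotient_curve(0.7, variant = "unimodal", kind = "variance",
                       n_points = 101)
  expect_identical(count_local_extrema(qc), 0L)
  expect_error(count_local_extrema(data.frame(value = c(1, 2, 1))),
               "at least 5")
})

test_that("the unimodal-variant Q_V is the constant 4s(2-s)", {
  for (s in c(0.3, 0.9, 1.3, 1.8)) {
    qc <- quotient_curve(s, variant = "unimodal", kind = "variance",
                         n_points = 101)
    expect_equal(qc$value, rep(4 * s * (2 - s), nrow(qc)), tolerance = 1e-12)
  }
  # whereas the Shannon curve varies
  qc <- quotient_curve(0.5, kind = "variance", n_points = 101)
  expect_gt(diff(range(qc$value)), 0.1)
})

test_that("curves serialize to a commented delimited table and back", {
  qc <- quotient_curve(0.5, kind = "sigma", n_points = 11)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_quotient_curve(qc, path)
  lines <- readLines(path)
  expect_match(lines[1], "^# s=0.5 variant=shannon")
  back <- utils::read.delim(path, comment.char = "#")
  expect_equal(nrow(back), nrow(qc))
  expect_equal(back$value, qc$value, tolerance = 1e-9)
  expect_true(all(back$quotient_kind == "sigma"))
  # csv on request
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_quotient_curve(qc, path2, format = "csv")
  back2 <- utils::read.csv(path2, comment.char = "#")
  expect_equal(back2$p10, qc$p10, tolerance = 1e-9)
})

test_that("boundary and out-of-range p10 are rejected with guidance", {
  expect_error(q_sigma(0.5, 0.5), "boundary_limit")
  expect_error(q_sigma(0.5, 0), "strictly inside")
  expect_error(q_variance(1.5, 0.4), "strictly inside")
  expect_error(q_sigma(2.5, 0.5), "degenerate")
})
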