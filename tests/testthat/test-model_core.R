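test_that("a minimal document parses into the smallest valid model", {
  m <- parse_model("
    state x1
    param th1
    ddt x1 = -th1*x1
    output y1 = x1
  ")
  expect_s3_class(m, "mosid_model")
  expect_length(m$state_names, 1)
  expect_length(m$param_names, 1)
  expect_length(m$outputs, 1)
  expect_identical(unknown_ic_states(m), "x1")   # bare state line = unknown IC
  expect_identical(unknown_names(m), c("th1", "x1(0)"))
  expect_identical(n_unknowns(m), 2L)
})

test_that("undeclared symbols and duplicate names are parse errors naming the culprit", {
  expect_error(parse_model("
    state x1
    param th1
    ddt x1 = -th1*x1 + z
    output y1 = x1
  "), "'z'")
  expect_error(parse_model("
    state x1
    state x1
    ddt x1 = -x1
    output y1 = x1
  "), "duplicate state")
  expect_error(parse_model("
    state x1
    param x1
    ddt x1 = -x1
    output y1 = x1
  "), "already used")
  expect_error(parse_model("
    state x1
    ddt x1 = abs(x1)
    output y1 = x1
  "), "abs")
})

test_that("parse/serialize round trip preserves the model", {
  for (nm in zoo_models()) {
    m <- builtin_model(nm)
    m2 <- parse_model(format_model(m))
    expect_identical(m2$state_names, m$state_names, info = nm)
    expect_identical(m2$param_names, m$param_names, info = nm)
    expect_equal(m2$init, m$init, info = nm)
    expect_equal(m2$param_nominal, m$param_nominal, info = nm)
    expect_equal(m2$constants, m$constants, info = nm)
    expect_equal(m2$time, m$time, info = nm)
    expect_identical(m2$grid_n, m$grid_n, info = nm)
    expect_identical(lapply(m2$rhs, deparse1), lapply(m$rhs, deparse1), info = nm)
    expect_identical(lapply(m2$outputs, deparse1), lapply(m$outputs, deparse1), info = nm)
  }
})

test_that("the bundled non-rational JAK/STAT model matches its printed structure", {
  m <- builtin_model("jakstat_nonrational")
  expect_length(m$state_names, 14)
  expect_length(m$outputs, 8)
  # 20 rate parameters + unknown x2(0) (the 21st unknown)
  expect_identical(n_unknowns(m), 21L)
  expect_identical(unknown_ic_states(m), "x2")
  # 13th right-hand side carries the sine of x10
  expect_match(deparse1(m$rhs[["x13"]]), "sin\\(x10\\)")
  # fixed initial conditions as printed
  ics <- unname(m$init[m$state_names])
  expect_equal(ics[-2], c(1.3, 0, 1, 0, 2.8, 0, 165, 0, 0, 0.34, 0, 0, 0))
  expect_true(is.na(ics[2]))
  # sensors include the parameter-scaled state sums
  expect_identical(deparse1(m$outputs$y2), "th16 * (x3 + x4 + x5 + x12)")
  expect_identical(deparse1(m$outputs$y3), "th17 * (x4 + x5)")
})

test_that("builtin_model rejects unknown names and lists the registry", {
  expect_error(builtin_model("nosuchmodel"), "jakstat_nonrational")
  m <- builtin_model("toy_sum")
  expect_identical(deparse1(m$rhs$x1), "-(th1 + th2) * x1")
})

test_that("every zoo model passes symbol validation", {
  for (nm in zoo_models()) expect_no_error(validate_model(builtin_model(nm)))
})

test_that("nominal point draws are deterministic, ranged, and honour declared nominals", {
  m <- builtin_model("toy_sum")
  p1 <- draw_nominal_point(m, 7)[[1]]
  p2 <- draw_nominal_point(m, 7)[[1]]
  expect_identical(p1, p2)
  # declared nominal values come back as the first point
  expect_equal(as.numeric(p1), c(0.7, 0.4, 2))

  # a model without nominals: all entries drawn in [0.1, 10], points distinct
  m0 <- parse_model("
    state x1
    param th1
    param th2
    ddt x1 = -th1*x1 - th2*x1
    output y1 = x1
  ")
  pts <- draw_nominal_point(m0, 7, 3)
  expect_length(pts, 3)
  for (p in pts) {
    expect_true(all(p >= 0.1 & p <= 10))
    expect_named(p, c("th1", "th2", "x1(0)"))
  }
  expect_gt(max(abs(pts[[1]] - pts[[2]])), 0)
  expect_gt(max(abs(pts[[2]] - pts[[3]])), 0)
})

test_that("fixture generator plants the documented correlations reproducibly", {
  fx1 <- make_correlated_fixture("product-pair", n = 3, p = 4, seed = 11)
  fx2 <- make_correlated_fixture("product-pair", n = 3, p = 4, seed = 11)
  expect_identical(format_model(fx1$model), format_model(fx2$model))
  expect_identical(fx1$planted, c("th1", "th2"))
  # parameters enter only through the planted combination
  expect_match(deparse1(fx1$model$rhs$x1), "th1 \\* th2")

  fx3 <- make_correlated_fixture("output-scale", n = 2, p = 3, seed = 3)
  expect_identical(fx3$planted, c("th1", "x1(0)"))
  expect_identical(deparse1(fx3$model$outputs$x1), "th1 * x1")

  expect_identical(make_correlated_fixture("none", n = 2, p = 2, seed = 1)$planted,
                   character(0))
  expect_error(make_correlated_fixture("product-pair", n = 1, p = 5, seed = 1),
               "too small")
  expect_error(make_correlated_fixture("sum-pair", n = 3, p = 1, seed = 1),
               "at least 2")
})

test_that("planted correlated sets are recovered exactly at 3 random regular points", {
  for (mech in c("product-pair", "sum-pair", "output-scale")) {
    fx <- make_correlated_fixture(mech, n = 3, p = 4, seed = 21)
    cons <- multipoint_consistency(fx$model, n_points = 3, seed = 9)
    expect_true(cons$consistent, info = mech)
    for (s in cons$supports) expect_setequal(s, fx$planted)
  }
  # empty mechanism: full rank at random points
  fx0 <- make_correlated_fixture("none", n = 3, p = 3, seed = 21)
  cons0 <- multipoint_consistency(fx0$model, n_points = 3, seed = 9)
  expect_true(cons0$consistent)
  expect_true(all(cons0$verdicts == "identifiable"))
})
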