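test_that("augmented system dimension is n + n*P", {
  sys <- assemble_extended_system(builtin_model("exp_decay"))
  expect_identical(sys$dim, 1L + 1L * 2L)
  sysj <- assemble_extended_system(builtin_model("jakstat_nonrational"))
  expect_identical(sysj$dim, 14L + 14L * 21L)
})

test_that("symbolic Jacobian of toy_sum is -(th1+th2)", {
  m <- builtin_model("toy_sum")
  sys <- assemble_extended_system(m)
  expect_equal(nrow(sys$jac_idx), 1)
  env <- list2env(list(th1 = 0.7, th2 = 0.4, x1 = 1))
  expect_equal(eval(sys$jac_call, env), -(0.7 + 0.4))
})

test_that("sensitivity trajectories match closed forms for exponential decay", {
  m <- builtin_model("exp_decay")
  pt <- c(th1 = 0.5, `x1(0)` = 2)
  traj <- simulate_sensitivities(m, pt, grid = c(0, 1, 2))
  # dx/dtheta(t) = -t x0 exp(-theta t)
  expect_equal(traj$sens[3, 1, 1], -2 * 2 * exp(-1), tolerance = 1e-6)
  # dx/dx0(t) = exp(-theta t); equals 1 at t0 (unit indicator)
  expect_equal(traj$sens[1, 1, 2], 1)
  expect_equal(traj$sens[, 1, 2], exp(-0.5 * c(0, 1, 2)), tolerance = 1e-8)
  # sensitivities to the rate parameter start at zero
  expect_equal(traj$sens[1, 1, 1], 0)
})

test_that("normalized matrix of exponential decay equals its closed form", {
  m <- builtin_model("exp_decay")
  traj <- simulate_sensitivities(m, c(th1 = 0.5, `x1(0)` = 2), grid = c(0, 1, 2))
  S <- build_sensitivity_matrix(traj, m, normalize = TRUE)
  expect_equal(unname(S$entries),
               cbind(c(0, -0.5, -1), c(1, 1, 1)), tolerance = 1e-8)
  expect_identical(S$column_labels, c("th1", "x1(0)"))
  expect_length(S$fallback_rows, 0)
})

test_that("the dh/dtheta term is included for parameter-scaled outputs", {
  # y = th2 * x1 with x1' = -th1 x1: dy/dth2 = x1 directly from h
  m <- parse_model("
    state x1 = 2
    param th1 = 0.5
    param th2 = 3
    ddt x1 = -th1*x1
    output y1 = th2*x1
    time 0 2 5
  ")
  pt <- draw_nominal_point(m, 1)[[1]]
  grid <- time_grid(m, 5)
  traj <- simulate_sensitivities(m, pt, grid)
  S <- build_sensitivity_matrix(traj, m, normalize = FALSE)
  x <- 2 * exp(-0.5 * grid)
  expect_equal(unname(S$entries[, "th2"]), x, tolerance = 1e-8)
})

test_that("raw output sensitivities agree with central differences on all zoo models", {
  for (nm in zoo_models()) {
    m <- builtin_model(nm)
    grid <- time_grid(m, 11)
    pt <- draw_nominal_point(m, 4)[[1]]
    traj <- simulate_sensitivities(m, pt, grid)
    S <- build_sensitivity_matrix(traj, m, normalize = FALSE)
    arr <- sensmat_array(S, output_labels(m))
    fd <- fd_output_sensitivities(m, pt, grid)
    scale <- max(abs(fd), 1)
    expect_lt(max(abs(arr - fd)) / scale, 1e-4)
  }
})

test_that("normalized matrix is invariant under output rescaling (non-fallback rows)", {
  for (seed in 1:3) {
    fx <- make_correlated_fixture("none", n = 3, p = 3, seed = seed)
    m <- fx$model
    m10 <- m
    m10$outputs <- lapply(m$outputs, function(e) bquote(10 * .(e)))
    pt <- draw_nominal_point(m, seed + 50)[[1]]
    traj <- simulate_sensitivities(m, pt)
    traj10 <- simulate_sensitivities(m10, pt)
    S <- build_sensitivity_matrix(traj, m)
    S10 <- build_sensitivity_matrix(traj10, m10)
    keep <- setdiff(seq_len(nrow(S$entries)), union(S$fallback_rows, S10$fallback_rows))
    expect_equal(S$entries[keep, ], S10$entries[keep, ], tolerance = 1e-9)
  }
})

test_that("rows with vanishing output values fall back to raw entries", {
  # y = x1 - 2 crosses zero at t = log(... ) and equals 0 nowhere on grid,
  # so use an output that is exactly 0 at t0: y = x2 with x2(0) = 0
  m <- parse_model("
    state x1 = 2
    state x2 = 0
    param th1 = 0.5
    ddt x1 = -th1*x1
    ddt x2 = th1*x1
    output y1 = x2
    time 0 2 5
  ")
  pt <- draw_nominal_point(m, 1)[[1]]
  traj <- simulate_sensitivities(m, pt)
  S <- build_sensitivity_matrix(traj, m, normalize = TRUE)
  expect_true(1 %in% S$fallback_rows)
  expect_false(2 %in% S$fallback_rows)
})

test_that("matrix shape follows M = m_active * (N+1) and P columns", {
  m <- builtin_model("cascade3")
  pt <- draw_nominal_point(m, 1)[[1]]
  grid <- time_grid(m, 13)
  traj <- simulate_sensitivities(m, pt, grid)
  for (act in list("x1", c("x1", "x3"), output_labels(m))) {
    S <- build_sensitivity_matrix(traj, m, active_outputs = act)
    expect_identical(dim(S$entries), c(length(act) * 13L, n_unknowns(m)))
  }
  expect_error(build_sensitivity_matrix(traj, m, active_outputs = character(0)),
               "nonempty")
  expect_error(build_sensitivity_matrix(traj, m, active_outputs = "nope"),
               "unknown output")
})

test_that("a too-short grid warns about unavoidable rank deficiency", {
  m <- builtin_model("cascade3")  # P = 6, one output on 1 grid... M = 2 < 6
  pt <- draw_nominal_point(m, 1)[[1]]
  traj <- simulate_sensitivities(m, pt, grid = c(0, 1))
  expect_warning(build_sensitivity_matrix(traj, m, active_outputs = "x1"),
                 "rank deficiency")
})

test_that("integration failures surface as errors, not silent NaNs", {
  m <- parse_model("
    state x1 = 1
    param th1 = 5
    ddt x1 = th1*x1^2
    output y1 = x1
    time 0 10 11
  ")
  pt <- c(th1 = 5)
  expect_error(suppressWarnings(simulate_sensitivities(m, pt)),
               "integration failed")
})
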