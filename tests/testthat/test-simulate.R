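test_that("step input produces the normo/hypercapnia concentration levels", {
  inp <- make_step_input(40, 50, t_init = 100, t_total = 200)
  expect_equal(unique(inp$values[inp$times < 100]), 1.099,
               tolerance = 1e-3 / 1.099)
  expect_equal(unique(inp$values[inp$times >= 100]), 1.3738,
               tolerance = 1e-3 / 1.3738)
  # derived pair with the same solubility
  inp2 <- make_step_input(30, 40, 50, 100)
  expect_equal(unique(inp2$values), pressure_to_concentration(c(30, 40)))
  # degenerate step is a constant signal
  inp3 <- make_step_input(40, 40, 50, 100)
  expect_equal(length(unique(inp3$values)), 1L)
  expect_error(make_step_input(-1, 50, 10, 20), "negative")
})

test_that("clinical chronogram follows the published phase table", {
  ph <- clinical_chronogram()
  hyp <- ph[ph$label == "hypocapnia", ]
  expect_equal(hyp$start, 1563)
  expect_equal(hyp$duration, 240)
  expect_equal(hyp$level, 0.824)
  expect_equal(max(ph$start + ph$duration), 4654)

  inp <- make_chronogram(ph)
  expect_equal(length(inp$times), 4653L)
  expect_equal(inp$values[inp$times == 1563], 0.824)
  expect_equal(inp$values[inp$times == 1562], 1.099)

  gap <- ph; gap$start[3] <- gap$start[3] + 5
  expect_error(make_chronogram(gap), "contiguous")
})

test_that("null input with null initial state stays identically zero", {
  g <- co2_grid()
  inp <- structure(list(times = 1:50, values = numeric(50), dt = 1,
                        label = "custom"), class = "co2_input")
  tr <- simulate_direct(g, inp)
  expect_equal(max(abs(tr$states)), 0)
  expect_equal(max(abs(tr$observations)), 0)
})

test_that("long constant-input runs converge to the linear steady state", {
  g <- co2_grid()
  level <- pressure_to_concentration(40)
  s <- settle_to_level(g, level, tol = 1e-6)
  ss <- steady_state(g, c(level, 0))
  expect_equal(s$state, as.vector(ss), tolerance = 1e-4)
  # partial pressure decreases monotonically from blood to collection
  H <- vapply(g$comp_of, function(j) g$compartments[[j]]$H, numeric(1))
  p_profile <- ss / H
  expect_true(all(diff(p_profile) < 1e-12))
  # the measured gas concentration is far below the Henry equilibrium level
  expect_lt(ss[g$obs_index], level / g$compartments[[1]]$H)
})

test_that("implicit Euler agrees with the matrix-exponential oracle at O(dt)", {
  skip_if_not_installed("Matrix")
  g <- co2_grid()
  level <- 1.099
  q <- c(level, 0)
  c_inf <- as.vector(steady_state(g, q))
  t_end <- 256
  exact <- c_inf + as.vector(Matrix::expm(g$F * t_end) %*% (-c_inf))
  err <- sapply(c(4, 2, 1), function(dt) {
    inp <- structure(list(times = seq(dt, t_end, by = dt),
                          values = rep(level, t_end / dt), dt = dt,
                          label = "custom"), class = "co2_input")
    tr <- simulate_direct(g, inp, dt = dt, keep_states = FALSE)
    max(abs(tr$final_state - exact))
  })
  expect_gt(err[1] / err[2], 1.6)
  expect_lt(err[1] / err[2], 2.4)
  expect_gt(err[2] / err[3], 1.6)
  expect_lt(err[2] / err[3], 2.4)
})

test_that("state norm stays bounded for large time steps (contractive solver)", {
  g <- co2_grid()
  level <- pressure_to_concentration(50)
  for (dt in c(10, 100)) {
    inp <- structure(list(times = seq(dt, 100 * dt, by = dt),
                          values = rep(level, 100), dt = dt,
                          label = "custom"), class = "co2_input")
    tr <- simulate_direct(g, inp, dt = dt, keep_states = FALSE)
    expect_true(all(is.finite(tr$final_state)))
    expect_lt(max(abs(tr$final_state)), 10 * level)
  }
})

test_that("observation noise is seeded, reproducible and leaves states clean", {
  g <- co2_grid()
  inp <- make_step_input(40, 50, 100, 300)
  t1 <- simulate_direct(g, inp, sigma_v2 = 1e-6, seed = 11)
  t2 <- simulate_direct(g, inp, sigma_v2 = 1e-6, seed = 11)
  t3 <- simulate_direct(g, inp, sigma_v2 = 1e-6, seed = 12)
  expect_identical(t1$observations, t2$observations)
  expect_false(identical(t1$observations, t3$observations))
  expect_identical(t1$states, t3$states)     # noise never touches states
  expect_equal(stats::sd(t1$observations - t1$y_clean), 1e-3,
               tolerance = 0.2)
})

test_that("trajectory CSV round trip is bit-exact", {
  g <- co2_grid()
  inp <- make_step_input(40, 50, 20, 60)
  tr <- simulate_direct(g, inp, sigma_v2 = 1e-8, seed = 3)
  f <- withr::local_tempfile(fileext = ".csv")
  write_trajectory(tr, f)
  tr2 <- read_trajectory(f)
  expect_identical(tr2$observations, tr$observations)
  expect_identical(unname(tr2$states), unname(tr$states))
  expect_identical(tr2$dt, tr$dt)
  expect_identical(tr2$noise_seed, 3L)
})

test_that("mismatched input sampling is rejected", {
  g <- co2_grid()
  inp <- make_step_input(40, 50, 20, 60, dt = 2)
  expect_error(simulate_direct(g, inp, dt = 1), "dt")
})
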