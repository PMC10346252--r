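test_that("AR(1) augmentation wires the input state into the blood row", {
  g <- co2_grid()
  aug <- augment_with_ar1(g, phi = 0)
  expect_equal(aug$n_aug, g$n + 1L)
  expect_equal(aug$F_aug[2, 1], unname(g$G[1, "boundary"]))
  expect_equal(aug$F_aug[1, ], c(0, numeric(g$n)))
  expect_equal(aug$F_aug[2:(g$n + 1), 2:(g$n + 1)], g$F)
  expect_equal(aug$obs_index, g$obs_index + 1L)

  # discrete self-transition of the input element under implicit Euler
  aug2 <- augment_with_ar1(g, phi = -0.0036)
  A <- diag(aug2$n_aug) - 1 * aug2$F_aug
  expect_equal(solve(A)[1, 1], 1 / (1 + 0.0036))
  expect_warning(augment_with_ar1(g, phi = 0.1), "unstable")
})

test_that("freezing the input state reproduces the direct model exactly", {
  g <- co2_grid()
  level <- pressure_to_concentration(45)
  K <- 300
  inp <- structure(list(times = seq_len(K), values = rep(level, K), dt = 1,
                        label = "custom"), class = "co2_input")
  direct <- simulate_direct(g, inp)

  aug <- augment_with_ar1(g, phi = 0)   # phi = 0: input state is persistent
  A <- diag(aug$n_aug) - 1 * aug$F_aug
  Ainv <- solve(A)
  c_k <- c(level, numeric(g$n))
  for (k in seq_len(K)) c_k <- Ainv %*% c_k
  expect_equal(as.vector(c_k[-1]), direct$final_state, tolerance = 1e-10)
  expect_equal(c_k[1], level)           # the AR(1) state never moved
})

test_that("prediction step: noise-free consistency and pure process noise", {
  g <- co2_grid()
  aug <- augment_with_ar1(g, 0)
  level <- 1.2
  x <- c(level, runif(g$n))
  cfg0 <- kalman_config(q_var = 0, r_var = 1e-6, q_structure = "full")
  pred <- kalman_predict(list(c = x, P = matrix(0, 14, 14)), aug, cfg0)
  A <- diag(14) - aug$F_aug
  expect_equal(pred$c, as.vector(solve(A, x)))   # exact implicit step
  expect_equal(pred$P, matrix(0, 14, 14))

  cfgq <- kalman_config(q_var = 1e-4, r_var = 1e-6, q_structure = "full")
  predq <- kalman_predict(list(c = x, P = matrix(0, 14, 14)), aug, cfgq)
  expect_equal(predq$P, diag(1e-4, 14))
})

test_that("update step limits: uninformative and perfect measurements", {
  g <- co2_grid()
  aug <- augment_with_ar1(g, 0)
  pred <- list(c = runif(14), P = diag(14))

  big_r <- kalman_config(r_var = 1e12)
  up <- kalman_update(pred, y = 5, aug, big_r)
  expect_equal(up$c, pred$c, tolerance = 1e-10)
  expect_lt(max(abs(up$gain)), 1e-10)

  tiny_r <- kalman_config(r_var = 1e-15)
  up2 <- kalman_update(pred, y = 5, aug, tiny_r)
  expect_equal(up2$c[aug$obs_index], 5, tolerance = 1e-9)

  # a non-finite sample is skipped and the prediction carried forward
  up3 <- kalman_update(pred, y = NaN, aug, kalman_config())
  expect_equal(up3$c, pred$c)
  expect_true(is.na(up3$innovation))
})

test_that("Joseph-form covariance stays symmetric positive semidefinite", {
  g <- co2_grid()
  aug <- augment_with_ar1(g, 0)
  cfg <- kalman_config()
  M <- capnoflow:::.kalman_matrices(aug, cfg)
  P <- diag(14)
  set.seed(21)
  y <- rnorm(5000, 0.07, 1e-3)
  I_n <- diag(14); io <- aug$obs_index
  for (k in seq_along(y)) {
    P <- M$Ainv %*% P %*% t(M$Ainv) + M$Q
    Kg <- P[, io] / (P[io, io] + cfg$r_var)
    IKH <- I_n; IKH[, io] <- IKH[, io] - Kg
    P <- IKH %*% P %*% t(IKH) + cfg$r_var * tcrossprod(Kg)
  }
  expect_lt(max(abs(P - t(P))), 1e-12)
  expect_gte(min(eigen(P, symmetric = TRUE, only.values = TRUE)$values),
             -1e-12)
})

test_that("constant steady observations drive the estimate to the true input", {
  g <- co2_grid()
  level <- pressure_to_concentration(40)
  y_ss <- sum(g$h * steady_state(g, c(level, 0)))
  aug <- augment_with_ar1(g, 0)
  inv <- run_inversion(rep(y_ss, 6000), aug, kalman_config())
  expect_equal(tail(inv$estimate, 1), level, tolerance = 2e-3)
  expect_lt(abs(tail(inv$innovation, 1)), 1e-8)
  # pressure output is the Henry-law conversion of the estimate
  expect_equal(inv$pressure, inv$estimate / co2_conversion_solubility())
})

test_that("empty observation series yields empty output", {
  g <- co2_grid()
  aug <- augment_with_ar1(g, 0)
  inv <- run_inversion(numeric(0), aug, kalman_config())
  expect_length(inv$estimate, 0)
})

test_that("inversion results serialize with their configuration", {
  g <- co2_grid()
  aug <- augment_with_ar1(g, -0.0036)
  inv <- run_inversion(rep(0.07, 50), aug, kalman_config())
  f <- withr::local_tempfile(fileext = ".csv")
  write_inversion(inv, times = 1:50, f)
  df <- utils::read.csv(f)
  expect_equal(df$estimate, inv$estimate)
  cfg <- jsonlite::read_json(paste0(f, ".json"))
  expect_equal(cfg$phi, -0.0036)
  expect_equal(cfg$q_var, 1e-8)
})
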