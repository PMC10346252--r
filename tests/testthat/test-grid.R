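test_that("grid placement follows the equidistant per-compartment spacing", {
  g <- build_grid(default_compartments())
  expect_equal(g$n, 13L)
  # blood: dz = 0.3/4; skin: 1.6e-3/4 above z = 0.3; outer point on top
  expect_equal(g$z[1:3], 0.075 * 1:3)
  expect_equal(g$z[4:6], 0.3 + 4e-4 * 1:3)
  expect_equal(g$z[7:9], 0.3016 + 0.0625 * 1:3)
  expect_equal(g$z[13], 0.3 + 1.6e-3 + 0.25 + 0.25)
  expect_equal(g$obs_index, 9L)

  g1 <- build_grid(list(compartment_spec("one", 1, 0.1, n_interior = 1)),
                   include_outer_point = FALSE)
  expect_equal(g1$n, 1L)

  expect_error(compartment_spec("bad", -1, 0.1), "invalid geometry")
  expect_error(compartment_spec("bad", 1, 0.1, n_interior = 0),
               "invalid geometry")
})

test_that("interface closure averages equal media and honours Henry jumps", {
  eq <- list(D = 0.1, dz = 0.05, H = 1)
  expect_equal(unname(interface_concentrations(1, 3, eq, eq)), c(2, 2))

  hj <- list(D = 0.1, dz = 0.05, H = 2)
  # solve the two continuity equations by hand: c- = 2/3, c+ = 4/3
  expect_equal(unname(interface_concentrations(1, 1, eq, hj)),
               c(2 / 3, 4 / 3))

  # flux continuity holds for arbitrary media
  set.seed(42)
  for (i in 1:20) {
    mb <- list(D = runif(1, 1e-4, 1), dz = runif(1, 1e-3, 0.2),
               H = runif(1, 0.2, 3))
    ma <- list(D = runif(1, 1e-4, 1), dz = runif(1, 1e-3, 0.2),
               H = runif(1, 0.2, 3))
    cb <- runif(1, 0, 5); ca <- runif(1, 0, 5)
    ci <- interface_concentrations(cb, ca, mb, ma)
    flux_below <- mb$D * (ci[["minus"]] - cb) / mb$dz
    flux_above <- ma$D * (ca - ci[["plus"]]) / ma$dz
    expect_equal(flux_below, flux_above, tolerance = 1e-12)
  }
})

test_that("single-compartment operator reduces to the convection-diffusion stencil", {
  D <- 0.05; h <- 1; ni <- 4
  g <- build_grid(list(compartment_spec("c", h, D, u = 0, n_interior = ni)),
                  include_outer_point = FALSE)
  g <- assemble_operator(g)
  dz <- h / (ni + 1)
  s <- D / dz^2
  expect_equal(g$F[2, 1:3], c(s, -2 * s, s))
  expect_equal(unname(g$G[1, "boundary"]), s)
  # top row: zero-diffusive-flux closure
  expect_equal(g$F[ni, (ni - 1):ni], c(2 * s, -2 * s))

  # with convection, interior rows carry the u/(2 dz) asymmetry
  u <- 0.01
  gu <- assemble_operator(build_grid(list(
    compartment_spec("c", h, D, u = u, n_interior = ni)),
    include_outer_point = FALSE))
  expect_equal(gu$F[2, 1], s + u / (2 * dz))
  expect_equal(gu$F[2, 3], s - u / (2 * dz))
})

test_that("device operator rows match hand-plugged stencil coefficients", {
  p <- capno_params()
  g <- co2_grid(p)
  dz <- 0.3 / 4
  am <- p$blood$D / dz^2 + p$blood$u / (2 * dz)
  a0 <- -2 * p$blood$D / dz^2
  ap <- p$blood$D / dz^2 - p$blood$u / (2 * dz)
  expect_equal(unname(g$G[1, "boundary"]), am)
  expect_equal(g$F[2, 1:3], c(am, a0, ap))
  expect_equal(g$F[1, 1], a0)
  expect_equal(g$F[1, 2], ap)
})

test_that("operator spectrum stays in the left half plane and A is expansive", {
  g <- co2_grid()
  ev <- eigen(g$F, only.values = TRUE)$values
  expect_lte(max(Re(ev)), 1e-12)
  for (dt in c(0.1, 1, 10)) {
    evA <- eigen(diag(g$n) - dt * g$F, only.values = TRUE)$values
    expect_true(all(Mod(evA) > 1))
  }
})

test_that("a steep convection cell triggers the Peclet warning", {
  bad <- list(compartment_spec("c", 1, D = 1e-4, u = 0.1, n_interior = 3))
  expect_warning(assemble_operator(build_grid(bad)), "Peclet")
})

test_that("sealed convection-free column conserves delta-z weighted mass", {
  g <- build_grid(toy_compartments())
  g <- assemble_operator(g, lower_bc = "neumann", upper_bc = "neumann")
  dt <- 0.5
  A <- diag(g$n) - dt * g$F
  Ainv <- solve(A)
  set.seed(7)
  c_k <- runif(g$n, 0.5, 2)
  m0 <- sum(g$weights * c_k)
  for (k in 1:10000) c_k <- Ainv %*% c_k
  expect_equal(sum(g$weights * c_k) / m0, 1, tolerance = 1e-10)
})

test_that("uniform-media sealed column keeps constants in the null space", {
  g <- build_grid(list(compartment_spec("a", 1, 0.1, n_interior = 4)),
                  include_outer_point = FALSE)
  g <- assemble_operator(g, lower_bc = "neumann", upper_bc = "neumann")
  expect_equal(max(abs(g$F %*% rep(1, g$n))), 0, tolerance = 1e-14)
})

test_that("steady state matches the analytic piecewise-linear Henry profile", {
  comps <- toy_compartments(n_interior = 5)
  g <- build_grid(comps, include_outer_point = FALSE)
  g <- assemble_operator(g, lower_bc = "dirichlet", upper_bc = "dirichlet")
  C0 <- 2; CL <- 0.3
  ss <- steady_state(g, c(C0, CL))

  # closed form: constant flux, linear in each layer, Henry jump at the
  # interface (independent derivation from the continuity equations)
  D1 <- comps[[1]]$D; L1 <- comps[[1]]$height
  D2 <- comps[[2]]$D; L2 <- comps[[2]]$height
  r <- comps[[2]]$H / comps[[1]]$H
  c_minus <- (D1 / L1 * C0 + D2 / L2 * CL) / (D1 / L1 + r * D2 / L2)
  c_plus <- r * c_minus
  z <- g$z
  expected <- ifelse(z <= L1,
                     C0 + (c_minus - C0) * z / L1,
                     c_plus + (CL - c_plus) * (z - L1) / L2)
  expect_equal(as.vector(ss), expected, tolerance = 1e-8)
})

test_that("operator dump is a readable plain-matrix CSV", {
  g <- co2_grid()
  f <- withr::local_tempfile(fileext = ".csv")
  write_operator(g, f)
  m <- as.matrix(utils::read.csv(f, header = FALSE))
  expect_equal(unname(m), unname(g$F), tolerance = 1e-12)
})
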