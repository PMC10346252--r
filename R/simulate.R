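# Forward (direct) integration of the semi-discrete transport model:
# implicit Euler stepping, exogenous input signals, observation extraction
# and seeded observation noise.

#' Step input signal between two capnia levels
#'
#' Piecewise-constant blood boundary concentration: `P_low` until `t_init`,
#' then `P_high` until `t_total`. Pressures are converted to concentrations
#' with the blood solubility at 42 degC.
#'
#' @param P_low,P_high partial pressures, mmHg (>= 0)
#' @param t_init time of the transition, s
#' @param t_total total signal duration, s
#' @param dt sampling interval, s
#' @param beta Ostwald solubility used for the conversion
#' @return object of class `co2_input`: uniform time grid (first sample at
#'   `t = dt`), concentration values (mol/m^3) and a label
#' @export
make_step_input <- function(P_low, P_high, t_init, t_total, dt = 1,
                            beta = co2_conversion_solubility()) {
  stop_if(P_low < 0 || P_high < 0, "invalid input: negative pressure")
  stop_if(t_init >= t_total, "invalid input: t_init must be < t_total")
  times <- seq(dt, t_total, by = dt)
  values <- ifelse(times < t_init,
                   pressure_to_concentration(P_low, beta),
                   pressure_to_concentration(P_high, beta))
  structure(list(times = times, values = values, dt = dt, label = "step",
                 t_init = t_init),
            class = "co2_input")
}

#' Piecewise-constant chronogram input
#'
#' Builds the blood concentration input from a table of contiguous phases.
#'
#' @param phases data frame with columns `label`, `start` (s), `duration`
#'   (s) and `level` (mol/m^3); phases must be contiguous and non-overlapping
#' @param dt sampling interval, s
#' @return a `co2_input` spanning start of the first phase to end of the last
#' @export
make_chronogram <- function(phases = clinical_chronogram(), dt = 1) {
  stopifnot(all(c("label", "start", "duration", "level") %in% names(phases)))
  o <- order(phases$start)
  phases <- phases[o, ]
  stop_if(any(phases$duration <= 0), "invalid chronogram: non-positive duration")
  ends <- phases$start + phases$duration
  if (nrow(phases) > 1 &&
      any(abs(phases$start[-1] - ends[-nrow(phases)]) > 1e-9))
    stop("invalid chronogram: phases must be contiguous (no gaps or overlaps)",
         call. = FALSE)
  t0 <- phases$start[1]
  t_end <- ends[nrow(phases)]
  times <- seq(t0, t_end - dt, by = dt)
  idx <- findInterval(times, phases$start)
  structure(list(times = times, values = phases$level[idx], dt = dt,
                 label = "chronogram", phases = phases),
            class = "co2_input")
}

#' Chronogram of a realistic clinical simulation
#'
#' Capnia phase sequence used for the clinical scenario: initialization and
#' extension phases at normocapnia around a hypocapnia dip and two
#' hypercapnia plateaus. Levels are in mol/m^3 with the matching partial
#' pressures in mmHg.
#'
#' @return data frame of phases (label, start, duration, level, pressure)
#' @export
clinical_chronogram <- function() {
  data.frame(
    label = c("initialization", "normocapnia1", "hypocapnia", "normocapnia2",
              "hypercapnia1", "hypercapnia2", "normocapnia3", "extension"),
    start = c(1, 1189, 1563, 1803, 2334, 2709, 3077, 3664),
    duration = c(1188, 374, 240, 531, 375, 368, 587, 990),
    level = c(1.099, 1.099, 0.824, 1.099, 1.236, 1.374, 1.099, 1.099),
    pressure = c(40, 40, 30, 40, 45, 50, 40, 40)
  )
}

#' One implicit Euler step
#'
#' Solves the implicit system `A c_{k+1} = c_k + dt * G q_{k+1}` with
#' `A = I - dt * F`. The solve is direct (no iteration); A is non-singular
#' for any dt > 0 because the spectrum of F lies in the closed left half
#' plane.
#'
#' @param c_k current state vector
#' @param q_next exogenous input vector at the next step
#' @param A implicit operator `I - dt*F`
#' @param G steering matrix
#' @param dt time step, s
#' @return state at the next step
#' @export
step_implicit <- function(c_k, q_next, A, G, dt) {
  solve(A, c_k + dt * as.vector(G %*% q_next))
}

#' Steady state under constant exogenous input
#'
#' Solves `F c + G q = 0`.
#'
#' @param grid assembled grid
#' @param q exogenous input vector (boundary concentration, ambient level)
#' @return steady-state concentration vector, mol/m^3
#' @export
steady_state <- function(grid, q) {
  solve(grid$F, -as.vector(grid$G %*% q))
}

# draw a noise vector without disturbing the caller's RNG stream
.seeded_noise <- function(n, sd, seed) {
  if (sd == 0) return(numeric(n))
  if (is.null(seed)) return(stats::rnorm(n, 0, sd))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_seed) assign(".Random.seed", old, envir = globalenv())
          else rm(".Random.seed", envir = globalenv()), add = TRUE)
  set.seed(seed)
  stats::rnorm(n, 0, sd)
}

#' Simulate the direct transport problem
#'
#' Integrates the state-space model forward with implicit Euler steps driven
#' by the input signal, extracts the scalar observation at the NDIR
#' measurement point and, optionally, adds seeded Gaussian observation noise
#' (noise is added to the observation only, never to the states).
#'
#' @param grid assembled grid ([co2_grid()])
#' @param input a `co2_input`
#' @param dt time step, s; must match the input sampling
#' @param sigma_v2 observation noise variance, (mol/m^3)^2
#' @param seed integer seed for the noise realization (recorded in the
#'   trajectory); `NULL` uses the current RNG stream
#' @param c0 initial state (default: zero vector)
#' @param keep_states store the full state history (set `FALSE` to save
#'   memory on long runs)
#' @return object of class `co2_trajectory`: times, state matrix (rows =
#'   time), noiseless and noisy observation series, noise metadata
#' @export
simulate_direct <- function(grid, input, dt = input$dt, sigma_v2 = 0,
                            seed = NULL, c0 = NULL, keep_states = TRUE) {
  stop_if(is.null(grid$F), "operator not assembled")
  stop_if(abs(dt - input$dt) > 1e-12,
          "invalid input: dt must match the input signal sampling")
  n <- grid$n
  K <- length(input$times)
  A <- diag(n) - dt * grid$F
  Ainv <- solve(A)
  Gd <- dt * grid$G
  C_amb <- if (!is.null(grid$params)) grid$params$air$C_ambient else 0
  c_k <- if (is.null(c0)) numeric(n) else c0
  states <- if (keep_states) matrix(NA_real_, K, n) else NULL
  y_clean <- numeric(K)
  obs <- grid$obs_index
  for (k in seq_len(K)) {
    c_k <- Ainv %*% (c_k + Gd %*% c(input$values[k], C_amb))
    if (keep_states) states[k, ] <- c_k
    y_clean[k] <- c_k[obs]
  }
  v <- .seeded_noise(K, sqrt(sigma_v2), seed)
  structure(list(times = input$times, states = states,
                 observations = y_clean + v, y_clean = y_clean,
                 input = input, dt = dt, sigma_v2 = sigma_v2,
                 noise_seed = seed, final_state = as.vector(c_k),
                 obs_index = obs),
            class = "co2_trajectory")
}

#' @export
print.co2_trajectory <- function(x, ...) {
  cat("<co2_trajectory> ", length(x$times), " samples, dt = ", x$dt,
      " s, observation noise variance = ", format(x$sigma_v2), "\n", sep = "")
  invisible(x)
}

#' Write / read a trajectory as CSV with a JSON sidecar
#'
#' The CSV holds time, the state columns `c_1..c_N` and the observation `y`;
#' the sidecar records dt, the noise variance and seed. The round trip is
#' bit-exact.
#'
#' @param traj a `co2_trajectory` (with states kept)
#' @param file CSV path; the sidecar is written to `<file>.json`
#' @export
write_trajectory <- function(traj, file) {
  stop_if(is.null(traj$states), "trajectory was run with keep_states = FALSE")
  df <- data.frame(time = traj$times, traj$states, y = traj$observations,
                   check.names = FALSE)
  names(df) <- c("time", paste0("c_", seq_len(ncol(traj$states))), "y")
  utils::write.csv(format(df, digits = 17, scientific = TRUE), file,
                   row.names = FALSE, quote = FALSE)
  meta <- list(dt = traj$dt, sigma_v2 = traj$sigma_v2,
               noise_seed = traj$noise_seed, obs_index = traj$obs_index)
  jsonlite::write_json(meta, paste0(file, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(file)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(file) {
  df <- utils::read.csv(file)
  meta <- jsonlite::read_json(paste0(file, ".json"))
  sc <- grep("^c_", names(df))
  structure(list(times = df$time, states = as.matrix(df[, sc]),
                 observations = df$y, y_clean = NULL, input = NULL,
                 dt = as.numeric(meta$dt), sigma_v2 = as.numeric(meta$sigma_v2),
                 noise_seed = meta$noise_seed,
                 obs_index = meta$obs_index,
                 final_state = as.numeric(df[nrow(df), sc])),
            class = "co2_trajectory")
}

#' Run the system to its settled state under a constant input
#'
#' Starting from `c0` (default zero), integrates at the given constant blood
#' concentration until the observation is within `tol` (relative) of its
#' steady level, in chunks. Used to initialize scenarios, mirroring the
#' initialization transient of the device after it is strapped on.
#'
#' @param grid assembled grid
#' @param level constant blood concentration, mol/m^3
#' @param dt time step, s
#' @param tol relative settling tolerance on the observation (default 0.1%)
#' @param c0 initial state
#' @param chunk chunk length in steps
#' @param max_time give up after this many seconds of model time
#' @return list with the settled state, the settling time (s) and the steady
#'   observation level
#' @export
settle_to_level <- function(grid, level, dt = 1, tol = 1e-3, c0 = NULL,
                            chunk = 4000, max_time = 2e5) {
  C_amb <- if (!is.null(grid$params)) grid$params$air$C_ambient else 0
  y_inf <- sum(grid$h * steady_state(grid, c(level, C_amb)))
  c_k <- if (is.null(c0)) numeric(grid$n) else c0
  t_done <- 0
  repeat {
    inp <- structure(list(times = seq(dt, chunk * dt, by = dt),
                          values = rep(level, chunk), dt = dt,
                          label = "custom"), class = "co2_input")
    tr <- simulate_direct(grid, inp, dt = dt, c0 = c_k, keep_states = FALSE)
    ok <- abs(tr$y_clean - y_inf) <= tol * abs(y_inf)
    if (any(ok)) {
      k <- which(ok)[1]
      # re-run the partial chunk to land exactly on the settling step
      inp2 <- structure(list(times = seq(dt, k * dt, by = dt),
                             values = rep(level, k), dt = dt,
                             label = "custom"), class = "co2_input")
      tr2 <- simulate_direct(grid, inp2, dt = dt, c0 = c_k, keep_states = FALSE)
      return(list(state = tr2$final_state, t_settle = t_done + k * dt,
                  y_steady = y_inf))
    }
    c_k <- tr$final_state
    t_done <- t_done + chunk * dt
    stop_if(t_done > max_time, "settling not reached within max_time")
  }
}
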