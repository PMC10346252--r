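# End-to-end scenario runners: the three-noise-level step study, the
# air-flow sweep, and the clinical chronogram with two regularity
# parameters.

#' Run the normocapnia-to-hypercapnia step scenario (direct problem)
#'
#' Starting from the zero state, the column is driven at the normocapnia
#' level until the observation settles within 0.1% of its steady level (the
#' initialization transient of the device after it is strapped on), then a
#' normocapnia baseline is held before the step to hypercapnia. The whole
#' record, initialization included, is simulated in one pass; the analysis
#' window over which metrics are computed starts after initialization, as a
#' wearer-side recording would.
#'
#' Default timing: dt = 1 s, 8400 s of baseline and 11600 s after the step
#' (20000 s analysis span), long enough for the estimate to settle fully;
#' the baseline fraction keeps the input's RMS level consistent with the
#' global-SNR normalization of the reference step experiment.
#'
#' @param grid assembled grid (default: the device grid)
#' @param P_low,P_high capnia levels, mmHg
#' @param t_baseline baseline duration before the step, s
#' @param t_after duration after the step, s
#' @param dt time step, s
#' @param sigma_v2 observation noise variance, (mol/m^3)^2
#' @param seed noise seed
#' @return list with the full trajectory (`traj`), the full input, the
#'   analysis-window index vector (`window`), the step time and the
#'   initialization duration
#' @export
run_step_scenario <- function(grid = co2_grid(), P_low = 40, P_high = 50,
                              t_baseline = 8400, t_after = 11600, dt = 1,
                              sigma_v2 = 0, seed = NULL) {
  C_low <- pressure_to_concentration(P_low)
  init <- settle_to_level(grid, C_low, dt = dt)
  t_init <- ceiling(init$t_settle / dt) * dt
  input <- make_step_input(P_low, P_high, t_init = t_init + t_baseline,
                           t_total = t_init + t_baseline + t_after, dt = dt)
  traj <- simulate_direct(grid, input, dt = dt, sigma_v2 = sigma_v2,
                          seed = seed)
  list(traj = traj, input = input, window = which(input$times > t_init),
       t_step = t_init + t_baseline, t_init = t_init, init = init,
       grid = grid)
}

# metrics shared by the study runners; all series restricted to the
# analysis window, with `t_step` the absolute step time
.step_metrics <- function(t, u_in, y, est, t_step, dt) {
  hyper_dur <- max(t) - t_step + dt
  mu <- settled_phase_mean(t, u_in, t_step, hyper_dur)
  mu_hat <- settled_phase_mean(t, est, t_step, hyper_dur)
  rmse <- aligned_rmse(u_in, est, dt = dt)
  base_sel <- t >= t_step - 0.1 * (t_step - min(t)) & t < t_step
  norm_level <- mean(est[base_sel])
  tr <- rise_time(t, est, norm_level, mu_hat)
  data.frame(
    mu_hypercapnia = mu,
    mu_hat_hypercapnia = mu_hat,
    rmse_aligned = as.numeric(rmse),
    perf_rel = perf_rel(mu, mu_hat),
    rsb_global = rsb_global(u_in, as.numeric(rmse)),
    t_rise = as.numeric(tr),
    td_dir = delay_by_xcorr(u_in, y, dt = dt),
    td_inv = delay_by_xcorr(y, est, dt = dt),
    td_global = delay_by_xcorr(u_in, est, dt = dt)
  )
}

#' Step study across observation noise levels
#'
#' Simulates the direct problem once (noiseless states), injects seeded
#' Gaussian observation noise at each requested variance, runs the Kalman
#' inversion and computes the full metric suite, one column per noise level.
#'
#' @param noise_variances observation noise variances, (mol/m^3)^2
#' @param seed base seed; level i uses `seed + i`
#' @param phi AR(1) regularity parameter for the inversion, s^-1
#' @param q_var,r_var Kalman noise settings
#' @param dt time step, s
#' @param params physical parameters
#' @param ... passed to [run_step_scenario()]
#' @return object of class `capno_step_study`: a data frame of metrics (one
#'   row per noise level) plus the underlying runs
#' @export
run_step_study <- function(noise_variances = c(0, 1e-8, 1e-6), seed = 1,
                           phi = 0, q_var = 1e-8, r_var = 1e-6, dt = 1,
                           q_structure = "input", params = capno_params(),
                           ...) {
  grid <- co2_grid(params)
  sc <- run_step_scenario(grid = grid, dt = dt, ...)
  aug <- augment_with_ar1(grid, phi = phi)
  cfg <- kalman_config(q_var = q_var, r_var = r_var, dt = dt,
                       q_structure = q_structure)
  rows <- list(); runs <- list()
  w <- sc$window
  for (i in seq_along(noise_variances)) {
    s2 <- noise_variances[i]
    v <- .seeded_noise(length(sc$traj$y_clean), sqrt(s2), seed + i)
    y <- sc$traj$y_clean + v
    inv <- run_inversion(y, aug, cfg)
    m <- .step_metrics(sc$input$times[w], sc$input$values[w], y[w],
                       inv$estimate[w], sc$t_step, dt)
    m$sigma_v2 <- s2
    rows[[i]] <- m
    runs[[i]] <- list(y = y, inversion = inv)
  }
  out <- do.call(rbind, rows)
  structure(list(metrics = out, scenario = sc, runs = runs,
                 phi = phi, seed = seed),
            class = "capno_step_study")
}

#' @export
print.capno_step_study <- function(x, ...) {
  cat("Step study (40 -> 50 mmHg), phi =", format(x$phi), "\n")
  m <- x$metrics
  lab <- c("mu hypercapnia (mol/m3)", "mu^ hypercapnia (mol/m3)",
           "rmse aligned (mol/m3)", "perf_rel (%)", "rsb_global (dB)",
           "t_r (s)", "td_dir (s)", "td_inv (s)", "td_global (s)")
  tab <- t(round(as.matrix(m[, 1:9]), 4))
  dimnames(tab) <- list(lab, paste0("var=", format(m$sigma_v2)))
  print(tab)
  invisible(x)
}

#' Air-flow sweep of the collection cell
#'
#' For each air flow, rebuilds the device grid, computes the steady
#' hypercapnia observation level (dilution), and measures the
#' cross-correlation delay and 10-90% rise time of the collection-cell
#' response to the capnia step. Illustrates the open-chamber compromise:
#' more flow gives faster response but a lower signal level.
#'
#' @param flows_ml_min air flows, mL/min (strictly increasing)
#' @param P_low,P_high capnia levels, mmHg
#' @param t_baseline,t_after step timing, s (shorter than the full study:
#'   only the collection-cell response is measured)
#' @param dt time step, s
#' @return data frame (class `capno_airflow_sweep`): flow, steady
#'   hypercapnia level at the observation point, collection-cell delay and
#'   rise time
#' @export
run_airflow_sweep <- function(flows_ml_min = c(0.1, 0.2, 0.5, 1, 2, 5, 10),
                              P_low = 40, P_high = 50,
                              t_baseline = 1200, t_after = 10800, dt = 1) {
  stop_if(any(diff(flows_ml_min) <= 0),
          "swept flows must be strictly increasing")
  C_hi <- pressure_to_concentration(P_high)
  rows <- lapply(flows_ml_min, function(f) {
    params <- capno_params(Q_air = f / 60)      # mL/min -> cm^3/s
    grid <- co2_grid(params)
    level <- sum(grid$h * steady_state(grid, c(C_hi, params$air$C_ambient)))
    i_coll <- max(which(grid$comp_of == 4L & seq_len(grid$n) < grid$n))
    init <- settle_to_level(grid, pressure_to_concentration(P_low), dt = dt)
    input <- make_step_input(P_low, P_high, t_baseline,
                             t_baseline + t_after, dt = dt)
    traj <- simulate_direct(grid, input, dt = dt, c0 = init$state)
    coll_sig <- traj$states[, i_coll]
    lev0 <- coll_sig[input$times == t_baseline - dt]
    lev1 <- mean(coll_sig[input$times > max(input$times) - 0.05 * t_after])
    data.frame(
      flow_ml_min = f,
      steady_level = level,
      delay = delay_by_xcorr(input$values, coll_sig, dt = dt),
      t_rise = as.numeric(rise_time(input$times, coll_sig, lev0, lev1))
    )
  })
  structure(do.call(rbind, rows), class = c("capno_airflow_sweep",
                                            "data.frame"))
}

#' Clinical chronogram study with two regularity parameters
#'
#' Simulates the clinical capnia chronogram through the transport model
#' (optionally with perturbed simulator parameters to emulate model
#' mismatch), adds observation noise, and runs the Kalman inversion once per
#' requested regularity parameter. Reports per-phase settled means, relative
#' performance and rise/fall times, plus global aligned RMSE, SNR and the
#' three delays.
#'
#' @param phi regularity parameters to compare, s^-1
#' @param sigma_v2 observation noise variance (default 1e-6)
#' @param seed noise seed
#' @param mismatch named list of multiplicative perturbations applied to the
#'   simulator only (fields `D_skin`, `D_blood`, `u_blood`, `Q_air`;
#'   default none): the inversion always uses the nominal model. A `Q_air`
#'   factor below 1 makes the simulated device less ventilated than the
#'   filter assumes, so the measured levels run high and the filter
#'   overestimates the blood concentration -- the situation in which a
#'   negative regularity parameter pays off
#' @param dt time step, s
#' @param q_var,r_var Kalman noise settings
#' @return object of class `capno_clinical_study` with elements `per_phase`
#'   and `global` (data frames keyed by phi)
#' @export
run_clinical_study <- function(phi = c(0, -0.0036), sigma_v2 = 1e-6,
                               seed = 1, mismatch = list(), dt = 1,
                               q_var = 1e-8, r_var = 1e-6) {
  params_sim <- if (!is.null(mismatch$Q_air))
    capno_params(Q_air = 16.7e-3 * mismatch$Q_air) else capno_params()
  if (!is.null(mismatch$D_skin))
    params_sim$skin$D <- params_sim$skin$D * mismatch$D_skin
  if (!is.null(mismatch$D_blood))
    params_sim$blood$D <- params_sim$blood$D * mismatch$D_blood
  if (!is.null(mismatch$u_blood))
    params_sim$blood$u <- params_sim$blood$u * mismatch$u_blood

  grid_sim <- co2_grid(params_sim)
  grid_mod <- co2_grid(capno_params())
  input <- make_chronogram(dt = dt)
  phases <- input$phases
  norm_level <- phases$level[1]
  init <- settle_to_level(grid_sim, norm_level, dt = dt)
  traj <- simulate_direct(grid_sim, input, dt = dt, sigma_v2 = sigma_v2,
                          seed = seed, c0 = init$state)
  cfg <- kalman_config(q_var = q_var, r_var = r_var, dt = dt)

  eval_phases <- phases[!phases$label %in% c("initialization", "extension"), ]
  # the initialization phase (filter cold start, device equilibration) is
  # excluded from the evaluation, which runs to the end of the record
  w <- which(input$times >= phases$start[2])
  per_phase <- list(); globals <- list(); inversions <- list()
  for (p in phi) {
    aug <- augment_with_ar1(grid_mod, phi = p)
    inv <- run_inversion(traj$observations, aug, cfg)
    # per-phase levels are read off the delay-compensated estimate (shifted
    # back by the global cross-correlation delay, as for the aligned RMSE);
    # otherwise short phases mostly see the previous phase's level
    d <- delay_by_xcorr(input$values[w], inv$estimate[w], dt = dt)
    k <- max(0L, as.integer(round(d / dt)))
    est <- c(inv$estimate[(1 + k):length(inv$estimate)],
             rep(inv$estimate[length(inv$estimate)], k))
    rows <- lapply(seq_len(nrow(eval_phases)), function(j) {
      ph <- eval_phases[j, ]
      mu <- settled_phase_mean(input$times, input$values, ph$start,
                               ph$duration)
      mu_hat <- suppressWarnings(
        settled_phase_mean(input$times, est, ph$start, ph$duration))
      prev_end <- ph$start - dt
      prev_lev <- est[input$times == prev_end]
      tr <- suppressWarnings(
        rise_time(input$times[input$times >= ph$start &
                              input$times < ph$start + ph$duration],
                  est[input$times >= ph$start &
                      input$times < ph$start + ph$duration],
                  prev_lev, mu_hat))
      data.frame(phi = p, phase = ph$label, mu = mu, mu_hat = mu_hat,
                 perf_rel = if (is.na(mu_hat)) NA_real_
                            else perf_rel(mu, mu_hat),
                 t_rise = as.numeric(tr))
    })
    per_phase[[as.character(p)]] <- do.call(rbind, rows)
    rmse <- aligned_rmse(input$values[w], inv$estimate[w], dt = dt)
    globals[[as.character(p)]] <- data.frame(
      phi = p,
      rmse_aligned = as.numeric(rmse),
      rsb_global = rsb_global(input$values[w], as.numeric(rmse)),
      td_dir = delay_by_xcorr(input$values[w], traj$observations[w], dt = dt),
      td_inv = delay_by_xcorr(traj$observations[w], inv$estimate[w], dt = dt),
      td_global = d
    )
    inversions[[as.character(p)]] <- inv
  }
  structure(list(per_phase = do.call(rbind, per_phase),
                 global = do.call(rbind, globals),
                 trajectory = traj, input = input,
                 inversions = inversions, mismatch = mismatch,
                 seed = seed),
            class = "capno_clinical_study")
}

#' @export
print.capno_clinical_study <- function(x, ...) {
  cat("Clinical chronogram study; mismatch:",
      if (length(x$mismatch)) paste(names(x$mismatch), "=",
                                    unlist(x$mismatch), collapse = ", ")
      else "none", "\n\nPer-phase metrics:\n")
  pp <- x$per_phase
  pp[, sapply(pp, is.numeric)] <- round(pp[, sapply(pp, is.numeric)], 4)
  print(pp, row.names = FALSE)
  cat("\nGlobal metrics:\n")
  g <- x$global
  g[, sapply(g, is.numeric)] <- round(g[, sapply(g, is.numeric)], 4)
  print(g, row.names = FALSE)
  invisible(x)
}

#' Serialize a study report to JSON and flat CSV
#'
#' @param study a step, airflow or clinical study object
#' @param json_file,csv_file output paths (either may be `NULL`)
#' @export
write_report <- function(study, json_file = NULL, csv_file = NULL) {
  tab <- if (inherits(study, "capno_step_study")) study$metrics
         else if (inherits(study, "capno_clinical_study")) study$per_phase
         else as.data.frame(study)
  if (!is.null(json_file))
    jsonlite::write_json(tab, json_file, dataframe = "rows",
                         auto_unbox = TRUE, digits = NA)
  if (!is.null(csv_file))
    utils::write.csv(tab, csv_file, row.names = FALSE)
  invisible(tab)
}
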