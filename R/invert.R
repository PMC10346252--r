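# Estimation of the blood CO2 concentration from the NDIR measurement
# series: the transport model is augmented with a first-order autoregressive
# prior on the unknown blood-input concentration, and a Kalman filter runs a
# prediction-correction loop on the augmented state.

#' Augment the transport model with an AR(1) blood-input state
#'
#' Element 1 of the augmented state is the (unknown) blood boundary
#' concentration, with continuous-time self-dynamics `phi` (s^-1) driven by
#' process noise; the first blood grid point couples to it with the former
#' Dirichlet steering coefficient `D/dz^2 + u/(2 dz)`. Eliminating element 1
#' and re-injecting it as a known exogenous input recovers the direct model
#' exactly.
#'
#' @param grid assembled grid ([co2_grid()])
#' @param phi AR(1) regularity parameter, s^-1; `phi = 0` is a random-walk
#'   prior, `phi < 0` damps the estimated input (a warning is issued for
#'   `phi > 0`, an unstable prior)
#' @return list of class `co2_augmented` with `F_aug`, `G_aug` (remaining
#'   exogenous inputs: the ambient column), observation selector `h_aug`,
#'   state dimension `n_aug = n + 1`
#' @export
augment_with_ar1 <- function(grid, phi = 0) {
  stop_if(is.null(grid$F), "operator not assembled")
  if (phi > 0) warning("phi > 0 gives an unstable input prior")
  n <- grid$n
  F_aug <- matrix(0, n + 1, n + 1)
  F_aug[1, 1] <- phi
  F_aug[2:(n + 1), 2:(n + 1)] <- grid$F
  F_aug[2:(n + 1), 1] <- grid$G[, "boundary"]
  G_aug <- matrix(0, n + 1, 1, dimnames = list(NULL, "ambient"))
  G_aug[2:(n + 1), 1] <- grid$G[, "ambient"]
  h_aug <- c(0, grid$h)
  structure(list(F_aug = F_aug, G_aug = G_aug, h_aug = h_aug,
                 obs_index = grid$obs_index + 1L, n_aug = n + 1L,
                 phi = phi, grid = grid),
            class = "co2_augmented")
}

#' Kalman filter configuration
#'
#' @param q_var process (modelization) noise variance, (mol/m^3)^2; the
#'   default 1e-8 follows the reference filter settings
#' @param r_var observation noise variance, (mol/m^3)^2 (default 1e-6)
#' @param dt time step, s
#' @param q_structure `"input"` (default) restricts the process noise to
#'   the blood-input element, attributing all model error to the unknown
#'   input signal -- this is what keeps the estimate in lock-step with the
#'   observation (zero inverse delay); `"full"` puts `q_var` on the whole
#'   augmented state (Q = q_var * I)
#' @param c0 initial state estimate (default: zero vector)
#' @param P0 initial covariance (default: identity)
#' @return list of class `kalman_config`
#' @export
kalman_config <- function(q_var = 1e-8, r_var = 1e-6, dt = 1,
                          q_structure = c("input", "full"),
                          c0 = NULL, P0 = NULL) {
  stop_if(q_var < 0 || r_var <= 0, "invalid parameter: q_var >= 0, r_var > 0")
  structure(list(q_var = q_var, r_var = r_var, dt = dt,
                 q_structure = match.arg(q_structure), c0 = c0, P0 = P0),
            class = "kalman_config")
}

.kalman_matrices <- function(aug, config) {
  n <- aug$n_aug
  A <- diag(n) - config$dt * aug$F_aug
  Ainv <- solve(A)
  Q <- if (config$q_structure == "full") diag(config$q_var, n)
       else { qm <- matrix(0, n, n); qm[1, 1] <- config$q_var; qm }
  list(A = A, Ainv = Ainv, Q = Q)
}

#' Kalman prediction step
#'
#' State extrapolation through the implicit scheme,
#' `A c_{k+1,k} = c_{k,k} + G q dt`, and covariance extrapolation
#' `P_{k+1,k} = A^-1 P A^-T + Q`.
#'
#' @param state list with `c` (estimate) and `P` (covariance)
#' @param aug augmented model from [augment_with_ar1()]
#' @param config a [kalman_config()]
#' @param q exogenous input vector (ambient concentration; default 0)
#' @return predicted `list(c, P)`
#' @export
kalman_predict <- function(state, aug, config, q = 0) {
  M <- .kalman_matrices(aug, config)
  c_pred <- as.vector(M$Ainv %*% (state$c + config$dt * aug$G_aug %*% q))
  P_pred <- M$Ainv %*% state$P %*% t(M$Ainv) + M$Q
  list(c = c_pred, P = P_pred)
}

#' Kalman measurement update
#'
#' Gain `K = P h (h' P h + R)^-1`, innovation `y - h'c`, a-posteriori state
#' and Joseph-form covariance
#' `P = (I - K h') P (I - K h')' + R K K'` (symmetric positive semidefinite
#' by construction). A non-finite measurement is skipped: the prediction is
#' carried forward unchanged.
#'
#' @param predicted `list(c, P)` from [kalman_predict()]
#' @param y scalar measurement, mol/m^3
#' @param aug augmented model
#' @param config a [kalman_config()]
#' @return list with `c`, `P`, `gain`, `innovation`
#' @export
kalman_update <- function(predicted, y, aug, config) {
  i_obs <- aug$obs_index
  if (!is.finite(y)) {
    return(list(c = predicted$c, P = predicted$P,
                gain = numeric(aug$n_aug), innovation = NA_real_))
  }
  P <- predicted$P
  S <- P[i_obs, i_obs] + config$r_var
  K <- P[, i_obs] / S
  innov <- y - predicted$c[i_obs]
  c_new <- predicted$c + K * innov
  IKH <- diag(aug$n_aug)
  IKH[, i_obs] <- IKH[, i_obs] - K
  P_new <- IKH %*% P %*% t(IKH) + config$r_var * tcrossprod(K)
  list(c = c_new, P = P_new, gain = K, innovation = innov)
}

#' Run the Kalman inversion over an observation series
#'
#' Prediction-correction loop over the measurement sequence; the estimated
#' blood CO2 concentration is element 1 of the a-posteriori state, and the
#' blood partial pressure follows from Henry's law (`P = C / beta`).
#'
#' @param y observation series, mol/m^3 (uniform sampling at `config$dt`)
#' @param aug augmented model from [augment_with_ar1()]
#' @param config a [kalman_config()]
#' @param q_ambient ambient input level fed to the prediction (default 0)
#' @param beta solubility for the pressure conversion
#' @param keep_covariance return the final covariance
#' @return object of class `co2_inversion`: per-step blood concentration
#'   estimate, pressure (mmHg), innovation and gain norm series
#' @export
run_inversion <- function(y, aug, config = kalman_config(),
                          q_ambient = 0, beta = co2_conversion_solubility(),
                          keep_covariance = FALSE) {
  K_steps <- length(y)
  n <- aug$n_aug
  out_c <- numeric(K_steps); out_innov <- numeric(K_steps)
  out_gain <- numeric(K_steps)
  if (K_steps == 0L)
    return(structure(list(estimate = out_c, pressure = out_c,
                          innovation = out_innov, gain_norm = out_gain,
                          config = config),
                     class = "co2_inversion"))
  M <- .kalman_matrices(aug, config)
  Gq <- config$dt * as.vector(aug$G_aug %*% q_ambient)
  c_k <- if (is.null(config$c0)) numeric(n) else config$c0
  P_k <- if (is.null(config$P0)) diag(n) else config$P0
  i_obs <- aug$obs_index
  I_n <- diag(n)
  for (k in seq_len(K_steps)) {
    # predict
    c_p <- as.vector(M$Ainv %*% (c_k + Gq))
    P_p <- M$Ainv %*% P_k %*% t(M$Ainv) + M$Q
    # update
    if (is.finite(y[k])) {
      S <- P_p[i_obs, i_obs] + config$r_var
      Kg <- P_p[, i_obs] / S
      innov <- y[k] - c_p[i_obs]
      c_k <- c_p + Kg * innov
      IKH <- I_n; IKH[, i_obs] <- IKH[, i_obs] - Kg
      P_k <- IKH %*% P_p %*% t(IKH) + config$r_var * tcrossprod(Kg)
    } else {
      c_k <- c_p; P_k <- P_p; Kg <- numeric(n); innov <- NA_real_
    }
    out_c[k] <- c_k[1]
    out_innov[k] <- innov
    out_gain[k] <- sqrt(sum(Kg^2))
  }
  structure(list(estimate = out_c, pressure = out_c / beta,
                 innovation = out_innov, gain_norm = out_gain,
                 final_state = c_k,
                 final_covariance = if (keep_covariance) P_k else NULL,
                 config = config, phi = aug$phi),
            class = "co2_inversion")
}

#' @export
print.co2_inversion <- function(x, ...) {
  cat("<co2_inversion> ", length(x$estimate), " steps, phi = ",
      format(x$phi), "; final estimate ",
      format(utils::tail(x$estimate, 1)), " mol/m^3\n", sep = "")
  invisible(x)
}

#' Write inversion results as CSV with a JSON config sidecar
#'
#' Columns: time, estimated blood concentration (mol/m^3), estimated blood
#' pressure (mmHg), innovation, gain norm.
#'
#' @param inv a `co2_inversion`
#' @param times time stamps, s
#' @param file CSV path; config sidecar goes to `<file>.json`
#' @export
write_inversion <- function(inv, times, file) {
  utils::write.csv(
    data.frame(time = times, estimate = inv$estimate,
               pressure_mmHg = inv$pressure, innovation = inv$innovation,
               gain_norm = inv$gain_norm),
    file, row.names = FALSE)
  cfg <- inv$config
  jsonlite::write_json(list(q_var = cfg$q_var, r_var = cfg$r_var,
                            dt = cfg$dt, q_structure = cfg$q_structure,
                            phi = inv$phi),
                       paste0(file, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(file)
}
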