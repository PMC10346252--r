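# Dual-wavelength NDIR measurement model: Beer-Lambert log-ratio inversion
# and the linear-quadratic calibration model with a non-integer power of the
# gas concentration, fitted by bounded Levenberg-Marquardt least squares.
#
# Wavelengths: detection at 4.26 um (a CO2 absorption peak), reference at
# 3.91 um (water-neutral). The differential measurement is the logarithm of
# the thermopile voltage ratio, which cancels the common-mode attenuation.

#' NDIR calibration model
#'
#' Parameters of the linear-quadratic response
#' `-ln(U_l1/U_l2) = l + m C^u + n C^(2u)`, where `l` is the blank intercept
#' `ln(U0_l2/U0_l1)` and `u_cal` the non-integer exponent (named to avoid
#' collision with the convection speed).
#'
#' @param intercept intercept `l`, dimensionless
#' @param m linear coefficient, per (mol/m^3)^u_cal (>= 0)
#' @param n quadratic coefficient, per (mol/m^3)^(2 u_cal) (>= 0)
#' @param u_cal exponent (> 0)
#' @param lambda_detect,lambda_ref wavelengths, um
#' @param k_co2 attenuation of CO2 at the detection wavelength, per mol/m^3
#'   (used by the purely linear Beer-Lambert mode)
#' @return object of class `ndir_calibration`
#' @export
ndir_calibration <- function(intercept = 0, m = 1, n = 0, u_cal = 1,
                             lambda_detect = 4.26, lambda_ref = 3.91,
                             k_co2 = m) {
  stop_if(m < 0 || n < 0 || u_cal <= 0,
          "invalid parameter: m, n must be >= 0 and u_cal > 0")
  stop_if(lambda_detect == lambda_ref,
          "invalid parameter: wavelengths must differ")
  structure(list(intercept = intercept, m = m, n = n, u_cal = u_cal,
                 lambda_detect = lambda_detect, lambda_ref = lambda_ref,
                 k_co2 = k_co2),
            class = "ndir_calibration")
}

#' Concentration from thermopile voltages (linear Beer-Lambert mode)
#'
#' `C = -ln((U_l1/U_l2) / (U0_l1/U0_l2)) / k_co2`: the log of the voltage
#' ratio referenced to the blank ratio, scaled by the CO2 attenuation at the
#' detection wavelength.
#'
#' @param U_l1,U_l2 thermopile read-outs with CO2 present (> 0)
#' @param U0_l1,U0_l2 blank read-outs without CO2 (> 0)
#' @param k_co2 attenuation coefficient, per mol/m^3 (> 0)
#' @return CO2 concentration in the measurement cell, mol/m^3
#' @export
concentration_from_logratio <- function(U_l1, U_l2, U0_l1, U0_l2, k_co2) {
  stop_if(any(c(U_l1, U_l2, U0_l1, U0_l2) <= 0),
          "invalid measurement: voltages must be positive")
  stop_if(k_co2 <= 0, "invalid parameter: k_co2 must be positive")
  -log((U_l1 / U_l2) / (U0_l1 / U0_l2)) / k_co2
}

#' Forward calibration response
#'
#' Evaluates `l + m C^u_cal + n C^(2 u_cal)`, the negative log voltage ratio
#' predicted for a given CO2 concentration. Monotone non-decreasing in C for
#' non-negative parameters; equals the intercept at C = 0.
#'
#' @param C concentration, mol/m^3 (>= 0, vectorized)
#' @param model an [ndir_calibration()]
#' @return predicted `-ln(U_l1/U_l2)`, dimensionless
#' @export
forward_logratio <- function(C, model) {
  stop_if(any(C < 0), "invalid input: negative concentration")
  model$intercept + model$m * C^model$u_cal + model$n * C^(2 * model$u_cal)
}

#' Synthetic thermopile voltages for a known concentration
#'
#' Inverse of the forward response: generates voltage pairs whose log-ratio
#' follows the calibration model, for building calibration fixtures. The
#' reference-channel voltage is held at its blank value.
#'
#' @param C concentrations, mol/m^3
#' @param model an [ndir_calibration()]; its intercept must equal
#'   `ln(U0_l2/U0_l1)` for the blanks supplied here
#' @param U0_l1,U0_l2 blank voltages
#' @return data frame with columns `C`, `U_l1`, `U_l2`
#' @export
simulate_ndir_voltages <- function(C, model, U0_l1 = 1, U0_l2 = 1) {
  L <- forward_logratio(C, model)     # = -ln(U_l1/U_l2)
  data.frame(C = C, U_l1 = U0_l2 * exp(-L), U_l2 = U0_l2)
}

#' Fit the NDIR calibration model
#'
#' Bounded Levenberg-Marquardt least squares of the linear-quadratic
#' response on supervised samples of known composition: minimizes
#' `sum_i (logratio_i + l + m C_i^u + n C_i^(2u))^2` where `logratio_i` is
#' the measured `ln(U_l1/U_l2)`. Non-negativity of `m`, `n`, `u_cal` is
#' enforced by bounds. Initialization uses the model's own linear limit
#' (`u_cal = 1`, `n = 0`, intercept and slope from an ordinary linear fit).
#'
#' @param C known concentrations, mol/m^3 (>= 4 distinct values)
#' @param logratio measured `ln(U_l1/U_l2)` per sample (note the sign: the
#'   model predicts its negative)
#' @param fit_intercept estimate the intercept (`TRUE`) or fix it
#' @param intercept fixed intercept value when `fit_intercept = FALSE`
#' @return an `ndir_calibration` with attributes `psi` (residual sum of
#'   squares at the optimum) and `fit` (the optimizer report)
#' @export
fit_calibration <- function(C, logratio, fit_intercept = TRUE,
                            intercept = 0) {
  stopifnot(length(C) == length(logratio))
  n_par <- 3 + as.integer(fit_intercept)
  stop_if(length(unique(C)) < n_par,
          "fit failure: need at least as many distinct concentrations as free parameters")
  y <- -logratio                       # target: l + m C^u + n C^(2u)
  lin <- stats::lm(y ~ C)
  l0 <- if (fit_intercept) unname(stats::coef(lin)[1]) else intercept
  m0 <- max(unname(stats::coef(lin)[2]), 1e-8)
  resid_fun <- function(p) {
    if (fit_intercept) {
      l <- p[1]; m <- p[2]; nq <- p[3]; u <- p[4]
    } else {
      l <- intercept; m <- p[1]; nq <- p[2]; u <- p[3]
    }
    l + m * C^u + nq * C^(2 * u) - y
  }
  p0 <- if (fit_intercept) c(l0, m0, 0, 1) else c(m0, 0, 1)
  lower <- if (fit_intercept) c(-Inf, 0, 0, 1e-6) else c(0, 0, 1e-6)
  fit <- minpack.lm::nls.lm(
    par = p0, fn = resid_fun, lower = lower,
    control = minpack.lm::nls.lm.control(ftol = 1e-15, ptol = 1e-15,
                                         gtol = 1e-10, maxiter = 500)
  )
  if (fit$info == 0 || fit$info == 9)
    warning("calibration fit did not converge: ", fit$message)
  p <- fit$par
  out <- if (fit_intercept)
    ndir_calibration(p[1], p[2], p[3], p[4])
  else
    ndir_calibration(intercept, p[1], p[2], p[3])
  attr(out, "psi") <- sum(resid_fun(p)^2)
  attr(out, "fit") <- fit
  out
}

#' Invert the fitted calibration for a measured log-ratio
#'
#' Solves `l + m C^u + n C^(2u) = -logratio` for C by monotone
#' root-bracketing (the forward response is non-decreasing).
#'
#' @param logratio measured `ln(U_l1/U_l2)`
#' @param model an `ndir_calibration`
#' @param C_max upper bracket, mol/m^3
#' @return concentration, mol/m^3
#' @export
invert_calibration <- function(logratio, model, C_max = 100) {
  target <- -logratio
  vapply(target, function(tg) {
    if (tg <= model$intercept) return(0)
    stats::uniroot(function(C) forward_logratio(C, model) - tg,
                   c(0, C_max), tol = 1e-12)$root
  }, numeric(1))
}

#' @export
print.ndir_calibration <- function(x, ...) {
  cat("<ndir_calibration> -ln(U1/U2) = ", format(x$intercept), " + ",
      format(x$m), " C^", format(x$u_cal), " + ", format(x$n), " C^",
      format(2 * x$u_cal), "\n", sep = "")
  if (!is.null(attr(x, "psi")))
    cat("  residual sum of squares at optimum: ", format(attr(x, "psi")),
        "\n", sep = "")
  invisible(x)
}

#' Write / read calibration samples and models
#'
#' Samples as CSV (`C`, `logratio`); fitted models as JSON.
#'
#' @param C,logratio calibration samples
#' @param file output path
#' @export
write_calibration_samples <- function(C, logratio, file) {
  utils::write.csv(data.frame(C = C, logratio = logratio), file,
                   row.names = FALSE)
  invisible(file)
}

#' @rdname write_calibration_samples
#' @export
read_calibration_samples <- function(file) utils::read.csv(file)

#' @rdname write_calibration_samples
#' @param model fitted `ndir_calibration`
#' @export
write_calibration_model <- function(model, file) {
  jsonlite::write_json(unclass(model)[c("intercept", "m", "n", "u_cal",
                                        "lambda_detect", "lambda_ref")],
                       file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' @rdname write_calibration_samples
#' @export
read_calibration_model <- function(file) {
  x <- jsonlite::read_json(file, simplifyVector = TRUE)
  ndir_calibration(x$intercept, x$m, x$n, x$u_cal,
                   x$lambda_detect, x$lambda_ref)
}
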