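# Spatial discretization of the four-compartment transport column and
# assembly of the finite-difference operator.
#
# Geometry convention: z increases from the blood compartment (bottom) to the
# collection cell (top); state indices 1..N follow increasing z. Each
# compartment contributes n_interior equidistant points at spacing
# dz_comp = height / (n_interior + 1); with the outer point included, one
# additional state sits on the top boundary of the collection cell and
# carries the zero-diffusive-flux closure.

#' Specification of one transport compartment
#'
#' @param name compartment label (conventionally one of `"blood"`, `"skin"`,
#'   `"meas"`, `"coll"`)
#' @param height compartment thickness along z, cm
#' @param D diffusion coefficient of CO2 in the compartment medium, cm^2/s
#' @param u mean convection speed along z, cm/s (0 for purely diffusive media)
#' @param H dimensionless Henry coefficient of the medium
#' @param n_interior number of interior grid points (>= 1)
#' @return object of class `compartment_spec`
#' @export
compartment_spec <- function(name, height, D, u = 0, H = 1, n_interior = 3) {
  stop_if(height <= 0 || D <= 0, "invalid geometry: height and D must be positive")
  stop_if(n_interior < 1, "invalid geometry: n_interior must be >= 1")
  structure(list(name = name, height = height, D = D, u = u, H = H,
                 n_interior = as.integer(n_interior),
                 dz = height / (n_interior + 1)),
            class = "compartment_spec")
}

#' Default compartment stack of the capnometry device
#'
#' Blood, stratum corneum, measurement cell and collection cell with the
#' tabulated 42 degC parameters, three interior points per compartment.
#'
#' @param params parameter list from [capno_params()]
#' @param n_interior interior points per compartment
#' @return list of four [compartment_spec()] objects, bottom to top
#' @export
default_compartments <- function(params = capno_params(), n_interior = 3) {
  list(
    compartment_spec("blood", params$blood$dz, params$blood$D,
                     params$blood$u, params$blood$H, n_interior),
    compartment_spec("skin", params$skin$dz, params$skin$D,
                     params$skin$u, params$skin$H, n_interior),
    compartment_spec("meas", params$air$dz_meas, params$air$D,
                     params$air$u_meas, params$air$H, n_interior),
    compartment_spec("coll", params$air$dz_coll, params$air$D,
                     params$air$u_coll, params$air$H, n_interior)
  )
}

#' Limit concentrations on the two sides of a media interface
#'
#' Diffusive-only interface closure: the one-sided diffusive fluxes balance
#' and the partial pressures (concentration over Henry coefficient) are
#' continuous across the interface, giving
#' \deqn{c^- = \frac{(D_-/\delta z_-) c_i + (D_+/\delta z_+) c_{i+1}}
#'            {D_-/\delta z_- + (H_+/H_-) D_+/\delta z_+}, \quad
#'       c^+ = (H_+/H_-)\, c^-.}
#' For identical media the closure reduces to the arithmetic average of the
#' neighbouring samples.
#'
#' @param c_below,c_above concentrations at the grid points below/above the
#'   interface, mol/m^3
#' @param media_below,media_above lists with fields `D` (cm^2/s), `dz` (cm)
#'   and `H` (dimensionless) for the medium on each side
#' @return numeric vector `c(minus, plus)`: the limit concentrations just
#'   below and just above the interface
#' @export
interface_concentrations <- function(c_below, c_above, media_below, media_above) {
  stop_if(media_below$D <= 0 || media_above$D <= 0 ||
          media_below$dz <= 0 || media_above$dz <= 0 ||
          media_below$H <= 0 || media_above$H <= 0,
          "invalid parameter: D, dz and H must be positive")
  a <- media_below$D / media_below$dz
  b <- media_above$D / media_above$dz
  r <- media_above$H / media_below$H
  c_minus <- (a * c_below + b * c_above) / (a + r * b)
  c(minus = c_minus, plus = r * c_minus)
}

# Interface closure weights: c_minus = wm_lo*c[i] + wm_hi*c[i+1],
# c_plus = r*c_minus. Used when folding the closure into the operator rows.
.interface_weights <- function(comp_below, comp_above) {
  a <- comp_below$D / comp_below$dz
  b <- comp_above$D / comp_above$dz
  r <- comp_above$H / comp_below$H
  list(wm_lo = a / (a + r * b), wm_hi = b / (a + r * b), r = r)
}

#' Build the discretized spatial grid
#'
#' Places `n_interior` equidistant points per compartment plus, optionally,
#' one outer point on the top boundary of the last compartment. With the
#' default four compartments and 3 interior points each, the state dimension
#' is N = 13.
#'
#' @param compartments list of [compartment_spec()] ordered bottom to top
#' @param include_outer_point place a state on the outer (top) boundary
#' @return object of class `co2_grid` with positions, per-point compartment
#'   index, quadrature weights for the mass functional, and the index of the
#'   NDIR observation point (the last measurement-cell point below the
#'   collection-cell interface)
#' @export
build_grid <- function(compartments, include_outer_point = TRUE) {
  stopifnot(length(compartments) >= 1)
  z0 <- 0
  z <- numeric(0); comp_of <- integer(0)
  for (j in seq_along(compartments)) {
    sp <- compartments[[j]]
    z <- c(z, z0 + sp$dz * seq_len(sp$n_interior))
    comp_of <- c(comp_of, rep(j, sp$n_interior))
    z0 <- z0 + sp$height
  }
  if (include_outer_point) {
    z <- c(z, z0)
    comp_of <- c(comp_of, length(compartments))
  }
  stop_if(any(diff(z) <= 0), "invalid geometry: positions must be strictly increasing")
  n <- length(z)
  # quadrature weights for the delta-z weighted mass functional; the top
  # boundary-closure row (factor-2 Neumann stencil) carries half a cell
  w <- vapply(comp_of, function(j) compartments[[j]]$dz, numeric(1))
  w[n] <- w[n] / 2
  # observation: last interior point of the measurement cell (compartment 3)
  obs <- if (length(compartments) >= 3) max(which(comp_of == 3L)) else n
  structure(list(z = z, n = n, comp_of = comp_of,
                 compartments = compartments,
                 include_outer_point = include_outer_point,
                 weights = w, obs_index = obs),
            class = "co2_grid")
}

#' Assemble the finite-difference operator and steering matrix
#'
#' Builds the linear operator F (s^-1) of the semi-discrete dynamics
#' dc/dt = F c + G q. Interior rows use the central convection-diffusion
#' stencil
#' \deqn{(D/\delta z^2 + u/2\delta z) c_{i-1} - (2D/\delta z^2) c_i +
#'       (D/\delta z^2 - u/2\delta z) c_{i+1};}
#' rows adjacent to a media interface substitute the diffusive-only interface
#' closure for the neighbour across the interface. The lower boundary is a
#' Dirichlet condition carried by `G[, "boundary"]` (exogenous blood
#' concentration); the top row is the diffusion-only zero-flux (Neumann)
#' closure. The second steering column carries the (default zero) ambient CO2
#' of the air drawn through the collection cell, or the top boundary value
#' when `upper_bc = "dirichlet"` is requested for validation set-ups.
#'
#' @param grid a [build_grid()] result
#' @param lower_bc `"dirichlet"` (exogenous concentration, the direct model)
#'   or `"neumann"` (sealed lower boundary)
#' @param upper_bc `"neumann"` (zero diffusive flux, the device model) or
#'   `"dirichlet"` (prescribed top concentration; requires
#'   `include_outer_point = FALSE`)
#' @return the grid with matrices `F` (n x n), `G` (n x 2) and observation
#'   selector `h` attached
#' @export
assemble_operator <- function(grid, lower_bc = c("dirichlet", "neumann"),
                              upper_bc = c("neumann", "dirichlet")) {
  lower_bc <- match.arg(lower_bc)
  upper_bc <- match.arg(upper_bc)
  stop_if(upper_bc == "dirichlet" && grid$include_outer_point,
          "upper Dirichlet requires include_outer_point = FALSE")
  comps <- grid$compartments
  n <- grid$n
  Fm <- matrix(0, n, n)
  G <- matrix(0, n, 2, dimnames = list(NULL, c("boundary", "ambient")))

  # Peclet check: central differencing oscillates for u*dz/(2D) >= 1
  pe <- vapply(comps, function(s) s$u * s$dz / (2 * s$D), numeric(1))
  if (any(pe >= 1))
    warning("cell Peclet number >= 1 in compartment(s) ",
            paste(vapply(comps[pe >= 1], `[[`, character(1), "name"),
                  collapse = ", "),
            ": central convection stencil may oscillate")

  for (i in seq_len(n)) {
    j <- grid$comp_of[i]
    sp <- comps[[j]]
    dz <- sp$dz
    am <- sp$D / dz^2 + sp$u / (2 * dz)   # weight of the lower neighbour
    a0 <- -2 * sp$D / dz^2
    ap <- sp$D / dz^2 - sp$u / (2 * dz)   # weight of the upper neighbour

    top_state <- i == n
    first_of_comp <- i == 1 || grid$comp_of[i - 1] != j
    last_of_comp <- !top_state && grid$comp_of[i + 1] != j

    if (top_state) {
      # zero-diffusive-flux closure, diffusion-only as in the mirrored stencil
      Fm[i, i - 1] <- 2 * sp$D / dz^2
      Fm[i, i] <- -2 * sp$D / dz^2
      next
    }

    Fm[i, i] <- Fm[i, i] + a0

    # lower neighbour
    if (i == 1) {
      if (lower_bc == "dirichlet") {
        G[1, "boundary"] <- am
      } else {
        # sealed: mirrored zero-flux row replaces the stencil entirely
        Fm[1, ] <- 0
        Fm[1, 1] <- -2 * sp$D / dz^2
        Fm[1, 2] <- 2 * sp$D / dz^2
        next
      }
    } else if (first_of_comp) {
      iw <- .interface_weights(comps[[j - 1]], sp)
      # neighbour below is the interface limit c_plus = r * c_minus
      Fm[i, i - 1] <- Fm[i, i - 1] + am * iw$r * iw$wm_lo
      Fm[i, i] <- Fm[i, i] + am * iw$r * iw$wm_hi
    } else {
      Fm[i, i - 1] <- Fm[i, i - 1] + am
    }

    # upper neighbour
    if (last_of_comp) {
      iw <- .interface_weights(sp, comps[[j + 1]])
      Fm[i, i] <- Fm[i, i] + ap * iw$wm_lo
      Fm[i, i + 1] <- Fm[i, i + 1] + ap * iw$wm_hi
    } else {
      Fm[i, i + 1] <- Fm[i, i + 1] + ap
    }
  }

  if (upper_bc == "dirichlet") {
    # last row was assembled as the top closure; rebuild it as an interior
    # row whose upper neighbour is the prescribed boundary value
    sp <- comps[[grid$comp_of[n]]]
    dz <- sp$dz
    Fm[n, ] <- 0
    Fm[n, n - 1] <- sp$D / dz^2 + sp$u / (2 * dz)
    Fm[n, n] <- -2 * sp$D / dz^2
    G[n, "ambient"] <- sp$D / dz^2 - sp$u / (2 * dz)
  } else if (length(comps) >= 4) {
    # The pumped air stream enters the collection cell laterally and leaves
    # at its upper edge. Along the 1D axis this inflow/outflow pair is a
    # washout exchange at rate u_coll / dz_coll on the collection-cell
    # interior points: fresh air at C_ambient replaces cell air, which is
    # what makes higher flows dilute the measured level.
    sp <- comps[[4]]
    if (sp$u > 0) {
      i_coll <- which(grid$comp_of == 4L & seq_len(n) < n)
      rate <- sp$u / sp$height
      for (i in i_coll) {
        Fm[i, i] <- Fm[i, i] - rate
        G[i, "ambient"] <- rate
      }
    }
  }

  # mass-functional weights follow the closures actually in effect
  if (lower_bc == "neumann")
    grid$weights[1] <- grid$weights[1] / 2
  if (upper_bc == "dirichlet") {
    j <- grid$comp_of[n]
    grid$weights[n] <- grid$compartments[[j]]$dz
  }

  h <- numeric(n); h[grid$obs_index] <- 1
  grid$F <- Fm; grid$G <- G; grid$h <- h
  grid$lower_bc <- lower_bc; grid$upper_bc <- upper_bc
  grid
}

#' Build and assemble the default device grid
#'
#' Convenience wrapper: [default_compartments()], [build_grid()] and
#' [assemble_operator()] in one call.
#'
#' @inheritParams default_compartments
#' @param include_outer_point place a state on the top boundary (N = 13 with
#'   the defaults)
#' @export
co2_grid <- function(params = capno_params(), n_interior = 3,
                     include_outer_point = TRUE) {
  g <- build_grid(default_compartments(params, n_interior),
                  include_outer_point = include_outer_point)
  g <- assemble_operator(g)
  g$params <- params
  g
}

#' @export
print.co2_grid <- function(x, ...) {
  cat("<co2_grid> ", x$n, " states over ",
      length(x$compartments), " compartments (",
      paste(vapply(x$compartments, `[[`, character(1), "name"),
            collapse = " | "),
      ")\n", sep = "")
  if (!is.null(x$F))
    cat("  operator assembled; observation at state ", x$obs_index,
        " (z = ", format(x$z[x$obs_index]), " cm)\n", sep = "")
  invisible(x)
}

#' Dump the assembled operator to plain-text CSV
#'
#' Writes F (and optionally G) as CSV matrices for inspection or
#' cross-language checks.
#'
#' @param grid assembled grid
#' @param file path for the operator CSV
#' @param steering_file optional path for the steering matrix CSV
#' @export
write_operator <- function(grid, file, steering_file = NULL) {
  stop_if(is.null(grid$F), "operator not assembled")
  utils::write.table(grid$F, file, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  if (!is.null(steering_file))
    utils::write.table(grid$G, steering_file, sep = ",", row.names = FALSE,
                       col.names = FALSE)
  invisible(file)
}
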