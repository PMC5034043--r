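#' Deterministic configuration integral of a toy system
#'
#' Midpoint-rule quadrature of the ligand configuration integral
#' \deqn{Z(\lambda) = \int_{box} e^{-\lambda U_{site}(r)/RT}\, d^3r}
#' and of the Boltzmann-averaged site energy at coupling `lambda`, on a
#' regular 3-D grid. Only position (O-atom) wells are supported: with
#' orientation-dependent H-wells the integral is five-dimensional and this
#' deterministic reference is not offered. The integrand is a sum of
#' smooth Gaussians, so the midpoint rule converges fast; the default grid
#' (96 points per axis in a 10 A box) is accurate to well below 0.01
#' kcal/mol in the derived free energies.
#'
#' @param system A [toy_host_guest()] with O-wells only.
#' @param thermo A [thermo_state()] (or temperature in kelvin).
#' @param lambda Coupling in `[0, 1]`.
#' @param n_grid Grid points per axis.
#' @return List with `z` (A^3), `mean_u` (kcal/mol), `v_box` (A^3).
#' @seealso [dg_decouple_quadrature()]
#' @export
site_config_integral <- function(system, thermo, lambda = 1, n_grid = 96) {
  thermo <- as_thermo(thermo)
  if (any(system$wells$atom == "H")) {
    stop("quadrature supports position (O-atom) wells only")
  }
  L <- system$box_lengths
  h <- L / n_grid
  gx <- (seq_len(n_grid) - 0.5) * h[1]
  gy <- (seq_len(n_grid) - 0.5) * h[2]
  gz <- (seq_len(n_grid) - 0.5) * h[3]
  cell <- prod(h)
  ow <- system$wells[system$wells$atom == "O", , drop = FALSE]
  z <- 0
  uw <- 0
  # accumulate one xy-plane at a time to keep memory flat
  xy <- expand.grid(x = gx, y = gy)
  for (zz in gz) {
    u <- numeric(nrow(xy))
    for (i in seq_len(nrow(ow))) {
      d2 <- (xy$x - ow$x[i])^2 + (xy$y - ow$y[i])^2 + (zz - ow$z[i])^2
      u <- u - ow$depth[i] * exp(-d2 / (2 * ow$width[i]^2))
    }
    w <- exp(-lambda * u / thermo$rt)
    z <- z + sum(w) * cell
    uw <- uw + sum(u * w) * cell
  }
  list(z = z, mean_u = uw / z, v_box = prod(L))
}

#' Quadrature reference for the decoupling free energy
#'
#' The exact (to quadrature accuracy) free-energy change of fully
#' decoupling the ligand from the site,
#' \deqn{\Delta G_{decouple} = G(\lambda=0) - G(\lambda=1)
#'       = RT \ln\left( Z(1) / Z(0) \right),}
#' with `Z(0) = V_box`. Positive for an attractive site. Serves as the
#' independent deterministic reference against which the sampled,
#' windowed Zwanzig estimate is validated.
#'
#' @inheritParams site_config_integral
#' @return Free energy in kcal/mol.
#' @export
dg_decouple_quadrature <- function(system, thermo, n_grid = 96) {
  thermo <- as_thermo(thermo)
  q <- site_config_integral(system, thermo, lambda = 1, n_grid = n_grid)
  thermo$rt * log(q$z / q$v_box)
}
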