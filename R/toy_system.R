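#' Toy host-guest system
#'
#' A rigid three-atom ligand (C-O-H, an alkylphenol-hydroxyl proxy) in a
#' rectangular box containing a composite Gaussian-well binding site. Each
#' well pulls on one ligand atom: position wells (`atom = "O"`) act on the
#' hydroxyl oxygen and model the overall site affinity; optional narrow
#' directional sub-wells (`atom = "H"`) act on the hydroxyl hydrogen and
#' model a hydrogen-bonding micro-site in front of an acceptor. The total
#' site-ligand potential is
#' \deqn{U_site = -\sum_i \epsilon_i \exp(-|r - c_i|^2 / (2 w_i^2)) \le 0,}
#' scaled by the coupling parameter lambda during alchemical decoupling
#' (`U_lambda = lambda * U_site`).
#'
#' The box spans `[0, box_lengths[d]]` in each dimension and confines the
#' oxygen (reference) atom by proposal rejection; there is no periodic wrap,
#' so the fully decoupled (lambda = 0) reference volume for the oxygen is
#' exactly `prod(box_lengths)`.
#'
#' @param box_lengths Numeric triple, box edge lengths in angstroms.
#' @param wells Data frame with columns `x, y, z` (center, angstrom),
#'   `depth` (epsilon_i, kcal/mol, >= 0), `width` (w_i, angstrom, > 0) and
#'   optionally `atom` (`"O"` or `"H"`, default `"O"`).
#' @param site_region List with `center` (angstrom triple) and `radius`
#'   (angstrom): the flat-bottom spherical region declared "bound"; its
#'   volume `4/3 pi R^3` enters the standard-state correction. Must lie
#'   fully inside the box.
#' @param hb_partners Optional data frame of static site atoms available as
#'   hydrogen-bond partners, columns `role` (`"acceptor"` or `"donor"`),
#'   `x, y, z`, and for donors the covalent hydrogen position
#'   `hx, hy, hz` (NA for acceptors).
#' @param d_oh,d_co O-H and C-O bond lengths of the rigid ligand (angstrom).
#' @param angle_coh C-O-H angle in degrees.
#' @return An object of class `toy_host_guest`.
#' @seealso [sample_trajectory()], [site_config_integral()],
#'   [toy_single_well()], [toy_three_well()], [demo_interfaces()]
#' @export
toy_host_guest <- function(box_lengths, wells, site_region,
                           hb_partners = NULL,
                           d_oh = 1.0, d_co = 1.4, angle_coh = 109.5) {
  box_lengths <- as.numeric(box_lengths)
  if (length(box_lengths) != 3L || any(!is.finite(box_lengths)) ||
      any(box_lengths <= 0)) {
    stop("`box_lengths` must be three positive finite numbers (angstrom)")
  }
  wells <- as.data.frame(wells)
  if (is.null(wells$atom)) wells$atom <- "O"
  needed <- c("x", "y", "z", "depth", "width", "atom")
  if (!all(needed %in% names(wells))) {
    stop("`wells` needs columns x, y, z, depth, width (and optionally atom)")
  }
  wells <- wells[needed]
  if (nrow(wells) > 0) {
    if (any(wells$depth < 0)) stop("well depths must be >= 0")
    if (any(wells$width <= 0)) stop("well widths must be > 0")
    if (!all(wells$atom %in% c("O", "H"))) stop("well atom must be 'O' or 'H'")
    if (any(!is.finite(as.matrix(wells[c("x", "y", "z", "depth", "width")])))) {
      stop("well parameters must be finite")
    }
  }
  sr_center <- as.numeric(site_region$center)
  sr_radius <- as.numeric(site_region$radius)
  if (length(sr_center) != 3L || length(sr_radius) != 1L || sr_radius <= 0) {
    stop("`site_region` must have a 3-vector center and a positive radius")
  }
  if (any(sr_center - sr_radius < 0) || any(sr_center + sr_radius > box_lengths)) {
    stop("`site_region` must lie fully inside the box")
  }
  if (!is.null(hb_partners)) {
    hb_partners <- as.data.frame(hb_partners)
    if (!all(c("role", "x", "y", "z") %in% names(hb_partners))) {
      stop("`hb_partners` needs columns role, x, y, z")
    }
    if (!all(hb_partners$role %in% c("acceptor", "donor"))) {
      stop("hb_partners roles must be 'acceptor' or 'donor'")
    }
    if (any(hb_partners$role == "donor") &&
        !all(c("hx", "hy", "hz") %in% names(hb_partners))) {
      stop("donor partners need hydrogen coordinates hx, hy, hz")
    }
  }
  if (d_oh <= 0 || d_co <= 0) stop("bond lengths must be positive")
  structure(
    list(box_lengths = box_lengths, wells = wells,
         site_region = list(center = sr_center, radius = sr_radius),
         hb_partners = hb_partners,
         d_oh = d_oh, d_co = d_co, angle_coh = angle_coh),
    class = "toy_host_guest"
  )
}

#' @export
print.toy_host_guest <- function(x, ...) {
  cat(sprintf("toy_host_guest: box %g x %g x %g A, %d well(s), V_site = %.1f A^3\n",
              x$box_lengths[1], x$box_lengths[2], x$box_lengths[3],
              nrow(x$wells), site_volume(x)))
  invisible(x)
}

#' Bound-site volume of a toy system
#'
#' Volume of the flat-bottom spherical site region, `4/3 pi R^3`, used in
#' the standard-state correction.
#'
#' @param system A [toy_host_guest()] object.
#' @return Volume in cubic angstroms.
#' @export
site_volume <- function(system) {
  4 / 3 * pi * system$site_region$radius^3
}

#' Site-ligand potential energy
#'
#' Evaluates the full-coupling (lambda = 1) site potential for given
#' oxygen (and, when H-wells are present, hydrogen) positions.
#'
#' @param system A [toy_host_guest()] object.
#' @param r_o Numeric matrix (n x 3) of oxygen positions, or a length-3
#'   vector.
#' @param r_h Optional matrix/vector of matching hydrogen positions;
#'   required if the system has H-wells.
#' @return Numeric vector of energies in kcal/mol (all <= 0).
#' @export
site_potential <- function(system, r_o, r_h = NULL) {
  r_o <- rbind3(r_o)
  u <- numeric(nrow(r_o))
  ow <- system$wells[system$wells$atom == "O", , drop = FALSE]
  hw <- system$wells[system$wells$atom == "H", , drop = FALSE]
  for (i in seq_len(nrow(ow))) {
    d2 <- (r_o[, 1] - ow$x[i])^2 + (r_o[, 2] - ow$y[i])^2 + (r_o[, 3] - ow$z[i])^2
    u <- u - ow$depth[i] * exp(-d2 / (2 * ow$width[i]^2))
  }
  if (nrow(hw) > 0) {
    if (is.null(r_h)) stop("system has H-wells; hydrogen positions required")
    r_h <- rbind3(r_h)
    for (i in seq_len(nrow(hw))) {
      d2 <- (r_h[, 1] - hw$x[i])^2 + (r_h[, 2] - hw$y[i])^2 + (r_h[, 3] - hw$z[i])^2
      u <- u - hw$depth[i] * exp(-d2 / (2 * hw$width[i]^2))
    }
  }
  u
}

rbind3 <- function(r) {
  if (is.null(dim(r))) r <- matrix(r, ncol = 3, byrow = TRUE)
  if (ncol(r) != 3L) stop("coordinates must be n x 3")
  r
}

#' Decoupling lambda schedule
#'
#' Ordered coupling values from 1 (fully coupled) to 0 (decoupled) defining
#' the alchemical windows, plus per-window sampling settings.
#'
#' @param n_windows Number of decoupling windows (adjacent lambda
#'   intervals). Default 24, the window count of the production protocol
#'   this toy stands in for.
#' @param samples_per_window Monte Carlo samples collected per window.
#' @param equilibration_per_window Discarded equilibration steps per window.
#' @param values Optional explicit lambda values (strictly monotone from 1
#'   to 0); overrides `n_windows`.
#' @return An object of class `lambda_schedule`.
#' @export
lambda_schedule <- function(n_windows = 24, samples_per_window = 10000,
                            equilibration_per_window = 1000, values = NULL) {
  if (is.null(values)) {
    values <- seq(1, 0, length.out = n_windows + 1L)
  }
  values <- as.numeric(values)
  if (length(values) < 2L) stop("schedule needs at least 2 lambda values")
  if (values[1] != 1 || values[length(values)] != 0) {
    stop("schedule endpoints must be exactly 1 and 0")
  }
  if (any(diff(values) >= 0)) stop("schedule must be strictly decreasing")
  if (samples_per_window < 1 || equilibration_per_window < 0) {
    stop("invalid per-window sample counts")
  }
  structure(
    list(values = values,
         samples_per_window = as.integer(samples_per_window),
         equilibration_per_window = as.integer(equilibration_per_window)),
    class = "lambda_schedule"
  )
}

#' Packaged single-well toy system
#'
#' One isotropic Gaussian well of depth 6 kcal/mol (width 1.3 A) centered
#' in a 10 A box. This is the reference system for checking the sampled
#' decoupling free energy against deterministic quadrature.
#'
#' @return A [toy_host_guest()] object.
#' @export
toy_single_well <- function() {
  toy_host_guest(
    box_lengths = c(10, 10, 10),
    wells = data.frame(x = 5, y = 5, z = 5, depth = 6, width = 1.3),
    site_region = list(center = c(5, 5, 5), radius = 3.5)
  )
}

#' Packaged three-well toy system
#'
#' Three overlapping Gaussian wells of unequal depth (4.5, 3.5, 2.5
#' kcal/mol) clustered near the box center, exercising multi-well
#' equilibration and the additivity of windowed free energies.
#'
#' @return A [toy_host_guest()] object.
#' @export
toy_three_well <- function() {
  toy_host_guest(
    box_lengths = c(10, 10, 10),
    wells = data.frame(
      x = c(4.3, 5.7, 5.0), y = c(5.0, 5.2, 6.3), z = c(5.0, 5.0, 5.2),
      depth = c(4.5, 3.5, 2.5), width = c(1.2, 1.0, 1.1)
    ),
    site_region = list(center = c(5, 5.5, 5), radius = 3.8)
  )
}

#' Engineered demo interfaces
#'
#' Four toy binding sites mimicking the four distinct subunit interfaces of
#' a heteropentameric receptor: two deep sites carrying a narrow
#' directional hydrogen-bond sub-well in front of a site acceptor
#' (expected high P_hb and low K_D) and two shallower sites with the same
#' acceptor geometry but no sub-well (expected low P_hb and weak binding).
#' Well depths are engineered so the dissociation constants span roughly
#' two orders of magnitude at 300 K.
#'
#' @return Named list of [toy_host_guest()] objects, with attribute
#'   `engineered` (data frame of the design: depth order, hb sub-well).
#' @export
demo_interfaces <- function() {
  mk <- function(depth, hb_depth) {
    wells <- data.frame(x = 5, y = 5, z = 5, depth = depth, width = 1.1,
                        atom = "O")
    if (hb_depth > 0) {
      # sub-well where the hydroxyl H sits when donating to the acceptor:
      # 1 A (the O-H bond) from the well center toward the acceptor
      wells <- rbind(wells, data.frame(x = 6.0, y = 5, z = 5,
                                       depth = hb_depth, width = 0.35,
                                       atom = "H"))
      # a 4+ kcal/mol directional sub-well keeps the hydroxyl H oriented at
      # the acceptor in ~90% of equilibrium frames
    }
    toy_host_guest(
      box_lengths = c(10, 10, 10),
      wells = wells,
      site_region = list(center = c(5, 5, 5), radius = 3.5),
      hb_partners = data.frame(role = "acceptor", x = 7.9, y = 5, z = 5,
                               hx = NA_real_, hy = NA_real_, hz = NA_real_)
    )
  }
  sites <- list(
    `deep-hb-1` = mk(14.5, 4.6),
    `deep-hb-2` = mk(13.5, 4.4),
    `shallow-1` = mk(11.5, 0),
    `shallow-2` = mk(10.5, 0)
  )
  attr(sites, "engineered") <- data.frame(
    site = names(sites),
    depth = c(14.5, 13.5, 11.5, 10.5),
    hb_subwell = c(TRUE, TRUE, FALSE, FALSE)
  )
  sites
}
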