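#' Per-window energy-difference samples
#'
#' Container for the alchemical perturbation energies of one decoupling
#' window: samples of `Delta U = U_lambda_to - U_lambda_from` (kcal/mol)
#' evaluated on equilibrium configurations of the `lambda_from` state.
#'
#' @param lambda_from,lambda_to Coupling values of the sampled and target
#'   states.
#' @param delta_u Numeric vector of energy differences (kcal/mol), finite,
#'   length >= 1.
#' @return An object of class `window_samples`.
#' @export
window_samples <- function(lambda_from, lambda_to, delta_u) {
  delta_u <- as.numeric(delta_u)
  if (length(delta_u) < 1L) stop("`delta_u` must contain at least one sample")
  if (any(!is.finite(delta_u))) stop("`delta_u` samples must be finite")
  structure(
    list(lambda_from = lambda_from, lambda_to = lambda_to,
         delta_u = delta_u, n = length(delta_u)),
    class = "window_samples"
  )
}

log_mean_exp <- function(x) {
  # log(mean(exp(x))) without overflow: shift by the max
  m <- max(x)
  m + log(mean(exp(x - m)))
}

#' Zwanzig exponential-averaging free energy of one window
#'
#' The exact free-energy difference between two states from samples of the
#' reference state:
#' \deqn{\Delta G = -RT \ln \langle e^{-\Delta U / RT} \rangle,}
#' evaluated with a max-shifted log-sum-exp so the result is finite
#' whenever the samples are.
#'
#' @param samples A [window_samples()] object (or bare numeric vector of
#'   `Delta U` in kcal/mol).
#' @param thermo A [thermo_state()] (or temperature in kelvin).
#' @return Free-energy difference in kcal/mol.
#' @examples
#' zwanzig_window(window_samples(1, 0.5, rep(1.0, 10)), thermo_state(300))
#' @export
zwanzig_window <- function(samples, thermo) {
  thermo <- as_thermo(thermo)
  du <- if (inherits(samples, "window_samples")) samples$delta_u
        else as.numeric(samples)
  if (length(du) < 1L) stop("empty sample list")
  if (any(!is.finite(du))) stop("`delta_u` samples must be finite")
  -thermo$rt * log_mean_exp(-du / thermo$rt)
}

check_contiguous <- function(lf, lt) {
  k <- length(lf)
  if (k > 1 && any(abs(lt[-k] - lf[-1]) > 1e-9)) {
    stop("windows do not tile a contiguous lambda path")
  }
  d <- lt - lf
  if (any(d == 0) || (any(d > 0) && any(d < 0))) {
    stop("windows must follow a strictly monotone lambda path")
  }
  d[1] < 0 # TRUE = decoupling direction (1 -> 0)
}

#' Accumulate windowed free energies along a decoupling path
#'
#' Sums the per-window Zwanzig estimates over a contiguous, strictly
#' monotone lambda path. The estimator is defined in the decoupling
#' direction (lambda decreasing); a path listed in the reverse (coupling)
#' direction denotes the same physical transformation traversed backward
#' and returns the negated decoupling total for the same samples.
#'
#' @param windows List of [window_samples()] tiling a monotone lambda path.
#' @param thermo A [thermo_state()] (or temperature in kelvin).
#' @return List with `dg_decouple` (kcal/mol, total along the listed path),
#'   and `per_window`: data frame of per-window lambda bounds, free energy,
#'   sample size, the mean-energy (Jensen) upper bound, and the maximum
#'   reduced perturbation `max |Delta U| / RT` as an overlap diagnostic.
#' @export
accumulate_decoupling <- function(windows, thermo) {
  thermo <- as_thermo(thermo)
  if (!length(windows)) stop("no windows supplied")
  lf <- vapply(windows, function(w) w$lambda_from, numeric(1))
  lt <- vapply(windows, function(w) w$lambda_to, numeric(1))
  decoupling <- check_contiguous(lf, lt)
  sgn <- if (decoupling) 1 else -1
  # in the coupling direction, evaluate the decoupling twin (negated
  # perturbations on the same samples) and negate the total
  dg <- vapply(windows, function(w) {
    sgn * zwanzig_window(sgn * w$delta_u, thermo)
  }, numeric(1))
  per_window <- data.frame(
    lambda_from = lf, lambda_to = lt, dg = dg,
    n = vapply(windows, function(w) w$n, numeric(1)),
    mean_du = vapply(windows, function(w) mean(w$delta_u), numeric(1)),
    max_abs_du_rt = vapply(windows, function(w) max(abs(w$delta_u)) / thermo$rt,
                           numeric(1))
  )
  list(dg_decouple = sum(dg), per_window = per_window)
}

#' Standard-state (site-volume) correction
#'
#' Entropic free-energy cost of transferring the ligand from the volume
#' available per molecule in the 1 M standard state (`v0`, by default the
#' physical value ~1660.5 A^3, commonly quoted as 1,660 A^3) to the bound
#' site volume: `-RT ln(V_site / V0)`. Positive when the site is smaller
#' than the standard volume.
#'
#' @param v_site Bound-site volume in cubic angstroms (> 0).
#' @param thermo A [thermo_state()] (or temperature in kelvin).
#' @param v0 Standard-state volume per molecule (cubic angstroms).
#' @return Correction in kcal/mol.
#' @examples
#' standard_state_correction(166, thermo_state(300), v0 = 1660) # RT ln 10
#' @export
standard_state_correction <- function(v_site, thermo, v0 = standard_volume_A3()) {
  thermo <- as_thermo(thermo)
  if (!is.numeric(v_site) || length(v_site) != 1L || !is.finite(v_site) ||
      v_site <= 0) {
    stop("`v_site` must be a single positive volume (A^3)")
  }
  -thermo$rt * log(v_site / v0)
}

#' Dissociation constant from the standard binding free energy
#'
#' Under the sign convention used throughout this package -- `dg0` is the
#' standard binding free energy, negative for favorable binding --
#' `K_D = exp(dg0 / RT) * 1 mol/L`. (Equivalently `K_D =
#' exp(-dG_unbind/RT)` with the positive unbinding free energy; micromolar
#' affinities correspond to `dg0` around -7 to -10 kcal/mol at 300 K.)
#'
#' @param dg0 Standard binding free energy in kcal/mol (finite).
#' @param thermo A [thermo_state()] (or temperature in kelvin).
#' @return Dissociation constant in mol/L.
#' @export
kd_from_delta_g <- function(dg0, thermo) {
  thermo <- as_thermo(thermo)
  if (!is.finite(dg0)) stop("`dg0` must be finite")
  exp(dg0 / thermo$rt)
}

#' Standard binding free energy from a dissociation constant
#'
#' Inverse of [kd_from_delta_g()]: `dg0 = RT ln(K_D / 1 M)`.
#'
#' @param kd Dissociation constant in mol/L (> 0).
#' @param thermo A [thermo_state()] (or temperature in kelvin).
#' @return Free energy in kcal/mol.
#' @export
delta_g_from_kd <- function(kd, thermo) {
  thermo <- as_thermo(thermo)
  if (!is.finite(kd) || kd <= 0) stop("`kd` must be a positive number (mol/L)")
  thermo$rt * log(kd)
}

#' Round to significant figures, halves away from zero
#'
#' Tables of binding constants conventionally print bands at one
#' significant figure with halves rounded away from zero; base
#' `signif()` rounds halves to even, so this explicit variant is used for
#' printed bands.
#'
#' @param x Numeric vector.
#' @param digits Significant figures (>= 1).
#' @return Rounded numeric vector.
#' @export
signif_half_up <- function(x, digits = 1) {
  out <- x
  nz <- is.finite(x) & x != 0
  e <- floor(log10(abs(x[nz]))) - (digits - 1)
  # tiny relative epsilon so decimal halves (e.g. 0.35) are not pushed
  # below the .5 boundary by binary representation error
  out[nz] <- sign(x[nz]) * floor(abs(x[nz]) / 10^e * (1 + 1e-12) + 0.5) * 10^e
  out
}

#' Uncertainty band of a dissociation constant
#'
#' Propagates a free-energy uncertainty `delta` (kcal/mol) into a
#' multiplicative band on `K_D`:
#' \deqn{(K_D e^{-\delta/RT},\; K_D e^{+\delta/RT}).}
#' With the conventional delta = 1 kcal/mol this reproduces the printed
#' "K_D range" style of affinity tables at one significant figure.
#'
#' @param kd Dissociation constant (mol/L or any fixed unit; the band is in
#'   the same unit), > 0.
#' @param delta Free-energy uncertainty in kcal/mol (>= 0). Default 1.
#' @param thermo A [thermo_state()] (or temperature in kelvin).
#' @param sig_figs Significant figures for the rounded band (default 1);
#'   `NULL` to skip rounding.
#' @return An object of class `kd_band`: `kd`, `delta`, raw `low`/`high`,
#'   and `low_rounded`/`high_rounded`.
#' @examples
#' b <- kd_uncertainty_band(2.0e-6, delta = 1, thermo = thermo_state(300))
#' c(b$low_rounded, b$high_rounded) * 1e6  # 0.4, 10 (micromolar)
#' @export
kd_uncertainty_band <- function(kd, delta = 1, thermo = thermo_state(),
                                sig_figs = 1) {
  thermo <- as_thermo(thermo)
  if (!is.finite(kd) || kd <= 0) stop("`kd` must be positive")
  if (!is.finite(delta) || delta < 0) stop("`delta` must be >= 0")
  f <- exp(delta / thermo$rt)
  low <- kd / f
  high <- kd * f
  structure(
    list(kd = kd, delta = delta, low = low, high = high,
         low_rounded = if (is.null(sig_figs)) low else signif_half_up(low, sig_figs),
         high_rounded = if (is.null(sig_figs)) high else signif_half_up(high, sig_figs)),
    class = "kd_band"
  )
}

#' @export
print.kd_band <- function(x, ...) {
  cat(sprintf("K_D = %.3g (band %.3g - %.3g; rounded %g - %g) [delta = %g kcal/mol]\n",
              x$kd, x$low, x$high, x$low_rounded, x$high_rounded, x$delta))
  invisible(x)
}

#' Assemble a standard binding free energy and dissociation constant
#'
#' End-to-end free-energy bookkeeping for one binding site: sums the
#' windowed decoupling free energy, applies the ligand solvation
#' correction (an injectable constant; 0 for the toy, whose "solvent" is
#' the empty box) and the standard-state site-volume correction, and
#' converts to a dissociation constant with its delta-uncertainty band.
#'
#' Sign convention: `dg0 = -(dg_decouple + dg_solv) + dg_volume`, negative
#' favorable, and `K_D = exp(dg0/RT) * 1 M`.
#'
#' @param windows List of [window_samples()] along the decoupling path
#'   (lambda 1 -> 0).
#' @param thermo A [thermo_state()] (or temperature in kelvin).
#' @param v_site Bound-site volume in cubic angstroms.
#' @param dg_solv Ligand solvation free-energy correction (kcal/mol).
#' @param delta Free-energy uncertainty for the K_D band (kcal/mol).
#' @param v0 Standard-state volume (cubic angstroms).
#' @return An object of class `free_energy_result` with components
#'   `dg_decouple`, `dg_volume`, `dg_solv`, `dg0`, `kd`, `band`,
#'   `per_window` and `diagnostics`.
#' @export
fep_estimate <- function(windows, thermo, v_site, dg_solv = 0, delta = 1,
                         v0 = standard_volume_A3()) {
  thermo <- as_thermo(thermo)
  acc <- accumulate_decoupling(windows, thermo)
  dg_volume <- standard_state_correction(v_site, thermo, v0 = v0)
  dg0 <- -(acc$dg_decouple + dg_solv) + dg_volume
  kd <- kd_from_delta_g(dg0, thermo)
  structure(
    list(dg_decouple = acc$dg_decouple, dg_volume = dg_volume,
         dg_solv = dg_solv, dg0 = dg0, kd = kd,
         band = kd_uncertainty_band(kd, delta, thermo),
         per_window = acc$per_window,
         diagnostics = list(
           max_abs_du_rt = max(acc$per_window$max_abs_du_rt),
           jensen_gap = sum(acc$per_window$mean_du) - acc$dg_decouple
         )),
    class = "free_energy_result"
  )
}

#' @export
print.free_energy_result <- function(x, ...) {
  cat(sprintf(paste0(
    "free_energy_result:\n",
    "  dG_decouple = %8.3f kcal/mol  (%d windows)\n",
    "  dG_volume   = %8.3f kcal/mol\n",
    "  dG_solv     = %8.3f kcal/mol\n",
    "  dG0         = %8.3f kcal/mol\n",
    "  K_D         = %.3g mol/L  (band %.3g - %.3g)\n"),
    x$dg_decouple, nrow(x$per_window), x$dg_volume, x$dg_solv, x$dg0,
    x$kd, x$band$low, x$band$high))
  invisible(x)
}

#' Read/write per-window samples as CSV
#'
#' Plain-text interchange for windowed perturbation energies: one row per
#' sample, columns `lambda_from`, `lambda_to`, `delta_u_kcal_mol`.
#'
#' @param windows List of [window_samples()].
#' @param path File path.
#' @return `write_windows_csv` returns `path` invisibly;
#'   `read_windows_csv` returns a list of [window_samples()].
#' @export
write_windows_csv <- function(windows, path) {
  df <- do.call(rbind, lapply(windows, function(w) {
    data.frame(lambda_from = w$lambda_from, lambda_to = w$lambda_to,
               delta_u_kcal_mol = w$delta_u)
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_windows_csv
#' @export
read_windows_csv <- function(path) {
  df <- utils::read.csv(path)
  needed <- c("lambda_from", "lambda_to", "delta_u_kcal_mol")
  if (!all(needed %in% names(df))) {
    stop("window CSV needs columns lambda_from, lambda_to, delta_u_kcal_mol")
  }
  key <- paste(df$lambda_from, df$lambda_to)
  lapply(unique(key), function(k) {
    sub <- df[key == k, ]
    window_samples(sub$lambda_from[1], sub$lambda_to[1], sub$delta_u_kcal_mol)
  })
}
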