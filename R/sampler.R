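wells_matrix <- function(system, atom) {
  w <- system$wells[system$wells$atom == atom, , drop = FALSE]
  m <- as.matrix(w[c("x", "y", "z", "depth", "width")])
  if (any(!is.finite(m))) stop("non-finite well parameters")
  m
}

start_state <- function(system) {
  ow <- system$wells[system$wells$atom == "O", , drop = FALSE]
  pos <- if (nrow(ow) > 0) {
    unlist(ow[which.max(ow$depth), c("x", "y", "z")], use.names = FALSE)
  } else {
    system$box_lengths / 2
  }
  c(pos, 1, 0, 0, 0) # identity orientation
}

check_steps <- function(step_sizes) {
  if (length(step_sizes) != 2L || any(!is.finite(step_sizes)) ||
      any(step_sizes <= 0)) {
    stop("`step_sizes` must be two positive numbers: (translation A, rotation rad)")
  }
}

#' Sample an equilibrium toy trajectory
#'
#' Runs Metropolis Monte Carlo for the rigid C-O-H ligand in the
#' Gaussian-well box under the coupled potential `U_lambda = lambda *
#' U_site` at the given temperature. Proposals mix local moves (uniform
#' translation of the oxygen plus rotation about a random axis) with
#' occasional whole-box jumps that carry the ligand to a uniformly random
#' position and orientation, which keeps multi-well systems mixing. The
#' oxygen atom is confined to the box by rejection. The run is
#' bit-reproducible: identical `(system, lambda, seed, n_frames)` give an
#' identical trajectory.
#'
#' @param system A [toy_host_guest()] object.
#' @param thermo A [thermo_state()] (or temperature in kelvin).
#' @param lambda Coupling in `[0, 1]`; 1 = fully coupled, 0 = ideal gas in
#'   the box.
#' @param n_frames Number of frames to record (>= 1).
#' @param step_sizes Numeric pair: translation half-width (angstrom) and
#'   rotation half-angle (radian) of the local proposal.
#' @param seed Integer seed; recorded in the trajectory metadata.
#' @param equilibration Discarded steps before the first recorded frame.
#' @param thin Record every `thin`-th step.
#' @param jump_prob Probability of a whole-box jump proposal.
#' @return An object of class `toy_trajectory`: atom roster (`atoms`),
#'   coordinates array `coords` of dimension `n_frames x n_atoms x 3`,
#'   per-frame site energy `u_site`, acceptance rate, and metadata.
#' @export
sample_trajectory <- function(system, thermo, lambda, n_frames,
                              step_sizes = c(0.6, 0.6), seed = 1L,
                              equilibration = 2000L, thin = 1L,
                              jump_prob = 0.25) {
  thermo <- as_thermo(thermo)
  if (!is.numeric(lambda) || lambda < 0 || lambda > 1) {
    stop("`lambda` must lie in [0, 1]")
  }
  if (n_frames < 1) stop("`n_frames` must be >= 1")
  check_steps(step_sizes)
  set.seed(as.integer(seed))
  res <- .mc_kernel(
    wells_matrix(system, "O"), wells_matrix(system, "H"),
    system$box_lengths, thermo$rt, lambda,
    as.integer(n_frames), as.integer(equilibration), as.integer(thin),
    step_sizes[1], step_sizes[2], jump_prob,
    start_state(system), c(system$d_oh, system$d_co, system$angle_coh),
    TRUE
  )
  build_trajectory(system, res, lambda = lambda, seed = seed)
}

build_trajectory <- function(system, res, lambda, seed) {
  atoms <- data.frame(
    id = c("O1", "H1", "C1"),
    role = c("donor", "hydrogen", "other"),
    parent = c(NA, "O1", NA),
    group = "ligand",
    stringsAsFactors = FALSE
  )
  n <- nrow(res$coords_o)
  coords_list <- list(O1 = res$coords_o, H1 = res$coords_h, C1 = res$coords_c)
  hp <- system$hb_partners
  if (!is.null(hp) && nrow(hp) > 0) {
    for (i in seq_len(nrow(hp))) {
      if (hp$role[i] == "acceptor") {
        id <- sprintf("SA%d", i)
        atoms <- rbind(atoms, data.frame(id = id, role = "acceptor",
                                         parent = NA, group = "site"))
        coords_list[[id]] <- matrix(rep(c(hp$x[i], hp$y[i], hp$z[i]), each = n),
                                    nrow = n)
      } else {
        id <- sprintf("SD%d", i); hid <- sprintf("SDH%d", i)
        atoms <- rbind(atoms,
                       data.frame(id = c(id, hid),
                                  role = c("donor", "hydrogen"),
                                  parent = c(NA, id), group = "site"))
        coords_list[[id]] <- matrix(rep(c(hp$x[i], hp$y[i], hp$z[i]), each = n),
                                    nrow = n)
        coords_list[[hid]] <- matrix(rep(c(hp$hx[i], hp$hy[i], hp$hz[i]),
                                         each = n), nrow = n)
      }
    }
  }
  coords <- array(NA_real_, dim = c(n, nrow(atoms), 3),
                  dimnames = list(NULL, atoms$id, c("x", "y", "z")))
  for (id in atoms$id) coords[, id, ] <- coords_list[[id]]
  structure(
    list(atoms = atoms, coords = coords, u_site = res$u_site,
         accept_rate = res$accept_rate, frame_interval = 1,
         lambda = lambda, seed = as.integer(seed)),
    class = "toy_trajectory"
  )
}

#' @export
print.toy_trajectory <- function(x, ...) {
  cat(sprintf(
    "toy_trajectory: %d frames, %d atoms, lambda = %g, seed = %d, acc = %.2f\n",
    n_frames(x), nrow(x$atoms), x$lambda, x$seed, x$accept_rate))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj A `toy_trajectory`.
#' @return Integer frame count.
#' @export
n_frames <- function(traj) dim(traj$coords)[1]

#' Per-window energy-difference samples along a decoupling schedule
#'
#' For each adjacent lambda pair `(lambda_k, lambda_k+1)` of the schedule,
#' equilibrates and samples the system at `lambda_k` and evaluates the
#' perturbation energy `Delta U = U_{lambda_k+1} - U_{lambda_k} =
#' (lambda_k+1 - lambda_k) * U_site` on those samples -- the averages
#' entering the Zwanzig exponential estimator. The Markov chain continues
#' from window to window (each window inherits the previous endpoint
#' state), mirroring sequential decoupling simulations.
#'
#' @inheritParams sample_trajectory
#' @param schedule A [lambda_schedule()].
#' @return List of `window_samples` objects (one per window, coupled to
#'   decoupled order).
#' @seealso [zwanzig_window()], [accumulate_decoupling()]
#' @export
window_work_samples <- function(system, thermo, schedule, seed = 1L,
                                step_sizes = c(0.6, 0.6), jump_prob = 0.4) {
  thermo <- as_thermo(thermo)
  if (!inherits(schedule, "lambda_schedule")) {
    stop("`schedule` must be a lambda_schedule object")
  }
  check_steps(step_sizes)
  set.seed(as.integer(seed))
  lam <- schedule$values
  state <- start_state(system)
  ow <- wells_matrix(system, "O")
  hw <- wells_matrix(system, "H")
  geom <- c(system$d_oh, system$d_co, system$angle_coh)
  windows <- vector("list", length(lam) - 1L)
  for (k in seq_len(length(lam) - 1L)) {
    res <- .mc_kernel(
      ow, hw, system$box_lengths, thermo$rt, lam[k],
      schedule$samples_per_window, schedule$equilibration_per_window, 1L,
      step_sizes[1], step_sizes[2], jump_prob, state, geom, FALSE
    )
    state <- res$final_state
    windows[[k]] <- window_samples(
      lambda_from = lam[k], lambda_to = lam[k + 1L],
      delta_u = (lam[k + 1L] - lam[k]) * res$u_site
    )
  }
  windows
}
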