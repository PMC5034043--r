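role_elem <- function(role) {
  c(donor = "O", hydrogen = "H", acceptor = "N", other = "C")[role]
}

#' Write / read toy trajectories as XYZ with a roles sidecar
#'
#' The trajectory coordinates go to a plain XYZ dialect whose per-frame
#' comment line carries the coupling and frame index
#' (`lambda=<x> frame=<k>`); atom roles, parent assignments, groups and
#' run metadata go to a JSON sidecar so the XYZ stays readable by standard
#' viewers. Per-frame site energies can be exported separately with
#' [write_energy_csv()].
#'
#' @param traj A `toy_trajectory`.
#' @param xyz_path Path of the XYZ file.
#' @param roles_path Path of the JSON sidecar.
#' @return `write_trajectory_xyz` invisibly returns `xyz_path`;
#'   `read_trajectory_xyz` returns a `toy_trajectory` (without site
#'   energies, which are not part of the XYZ dialect).
#' @export
write_trajectory_xyz <- function(traj, xyz_path, roles_path) {
  stopifnot(inherits(traj, "toy_trajectory"))
  atoms <- traj$atoms
  elems <- role_elem(atoms$role)
  n <- n_frames(traj)
  con <- file(xyz_path, "w")
  on.exit(close(con))
  for (f in seq_len(n)) {
    writeLines(as.character(nrow(atoms)), con)
    writeLines(sprintf("lambda=%.10g frame=%d", traj$lambda, f), con)
    writeLines(sprintf("%s %.6f %.6f %.6f", elems,
                       traj$coords[f, , 1], traj$coords[f, , 2],
                       traj$coords[f, , 3]), con)
  }
  jsonlite::write_json(
    list(atoms = atoms, frame_interval = traj$frame_interval,
         lambda = traj$lambda, seed = traj$seed),
    roles_path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(xyz_path)
}

#' @rdname write_trajectory_xyz
#' @export
read_trajectory_xyz <- function(xyz_path, roles_path) {
  meta <- jsonlite::read_json(roles_path, simplifyVector = TRUE)
  atoms <- as.data.frame(meta$atoms)
  atoms$parent <- as.character(atoms$parent)
  lines <- readLines(xyz_path)
  na <- nrow(atoms)
  block <- na + 2L
  if (length(lines) %% block != 0L) stop("malformed XYZ file")
  nf <- length(lines) %/% block
  coords <- array(NA_real_, dim = c(nf, na, 3),
                  dimnames = list(NULL, atoms$id, c("x", "y", "z")))
  for (f in seq_len(nf)) {
    body <- lines[((f - 1L) * block + 3L):((f - 1L) * block + block)]
    m <- do.call(rbind, strsplit(trimws(body), "\\s+"))
    coords[f, , ] <- matrix(as.numeric(m[, 2:4]), ncol = 3)
  }
  structure(
    list(atoms = atoms, coords = coords, u_site = NULL,
         accept_rate = NA_real_,
         frame_interval = meta$frame_interval,
         lambda = meta$lambda, seed = meta$seed),
    class = "toy_trajectory"
  )
}

#' Export per-frame site energies
#'
#' @param traj A `toy_trajectory` produced by [sample_trajectory()].
#' @param path CSV path; columns `frame`, `u_site_kcal_mol`.
#' @return `path`, invisibly.
#' @export
write_energy_csv <- function(traj, path) {
  if (is.null(traj$u_site)) stop("trajectory carries no energies")
  utils::write.csv(
    data.frame(frame = seq_along(traj$u_site), u_site_kcal_mol = traj$u_site),
    path, row.names = FALSE)
  invisible(path)
}
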