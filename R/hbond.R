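#' Geometric hydrogen-bond criterion
#'
#' The trajectory-analysis criterion used throughout the package: a
#' donor-acceptor pair is hydrogen bonded when the donor-acceptor distance
#' is at most `d_cut` and the deviation angle is at most `angle_cut`.
#' Ties at the exact cutoff count as bonded.
#'
#' Two angle conventions are supported and the choice is stored with the
#' criterion:
#' * `"hda_at_donor"` (default): the deviation is the angle H-D-A measured
#'   at the donor, i.e. how far the covalent D-H bond points away from the
#'   acceptor; 0 for ideal collinear geometry.
#' * `"dha_from_180"`: the deviation is `180 - angle(D-H-A)` measured at
#'   the hydrogen.
#'
#' @param d_cut Donor-acceptor distance cutoff in angstroms (default 3.3).
#' @param angle_cut Deviation-angle cutoff in degrees (default 40).
#' @param convention Angle convention tag (see above).
#' @return An object of class `hbond_criterion`.
#' @export
hbond_criterion <- function(d_cut = 3.3, angle_cut = 40,
                            convention = c("hda_at_donor", "dha_from_180")) {
  convention <- match.arg(convention)
  if (!is.finite(d_cut) || d_cut <= 0) stop("`d_cut` must be > 0")
  if (!is.finite(angle_cut) || angle_cut <= 0 || angle_cut > 180) {
    stop("`angle_cut` must lie in (0, 180]")
  }
  structure(list(d_cut = d_cut, angle_cut = angle_cut,
                 convention = convention),
            class = "hbond_criterion")
}

# vectorized geometry: D, H, A are n x 3 matrices
hbond_geometry <- function(D, H, A, convention) {
  d_da <- sqrt(rowSums((A - D)^2))
  if (convention == "hda_at_donor") {
    v1 <- H - D
    v2 <- A - D
  } else {
    v1 <- D - H
    v2 <- A - H
  }
  n1 <- sqrt(rowSums(v1^2))
  n2 <- sqrt(rowSums(v2^2))
  if (any(n1 == 0) || any(n2 == 0) || any(d_da == 0)) {
    stop("coincident points in hydrogen-bond geometry")
  }
  cosang <- pmin(1, pmax(-1, rowSums(v1 * v2) / (n1 * n2)))
  ang <- acos(cosang) * 180 / pi
  dev <- if (convention == "hda_at_donor") ang else 180 - ang
  list(d_da = d_da, deviation = dev)
}

#' Detect a hydrogen bond between one donor/hydrogen/acceptor triple
#'
#' @param donor,hydrogen,acceptor Length-3 coordinate vectors (angstrom);
#'   the hydrogen must be the one covalently attached to the donor.
#' @param criterion An [hbond_criterion()].
#' @return List with `bonded` (logical), `d_da` (donor-acceptor distance,
#'   angstrom) and `deviation` (deviation angle, degrees).
#' @examples
#' crit <- hbond_criterion()
#' detect_hbond(c(0, 0, 0), c(1, 0, 0), c(2.8, 0, 0), crit)$bonded  # TRUE
#' @export
detect_hbond <- function(donor, hydrogen, acceptor, criterion = hbond_criterion()) {
  stopifnot(inherits(criterion, "hbond_criterion"))
  pts <- rbind(donor, hydrogen, acceptor)
  if (any(!is.finite(pts))) stop("coordinates must be finite")
  g <- hbond_geometry(matrix(donor, 1), matrix(hydrogen, 1),
                      matrix(acceptor, 1), criterion$convention)
  list(bonded = g$d_da <= criterion$d_cut & g$deviation <= criterion$angle_cut,
       d_da = g$d_da, deviation = g$deviation)
}

# all candidate (donor, hydrogen, acceptor) triples between a ligand group
# and site partners, in both donation directions; the ligand hydroxyl
# oxygen (a donor) also acts as acceptor for site donors
candidate_triples <- function(atoms, ligand_ids, partner_ids) {
  if (!length(partner_ids)) stop("empty partner set")
  if (!length(ligand_ids)) stop("empty ligand group")
  unknown <- setdiff(c(ligand_ids, partner_ids), atoms$id)
  if (length(unknown)) stop("unknown atom ids: ", paste(unknown, collapse = ", "))
  rows <- function(ids) atoms[atoms$id %in% ids, , drop = FALSE]
  lig <- rows(ligand_ids)
  par <- rows(partner_ids)
  triples <- list()
  # ligand donates: ligand donor + its hydrogen vs partner acceptors
  lig_h <- lig[lig$role == "hydrogen" & lig$parent %in% lig$id[lig$role == "donor"], ,
               drop = FALSE]
  for (acc in par$id[par$role == "acceptor"]) {
    for (i in seq_len(nrow(lig_h))) {
      triples[[length(triples) + 1L]] <-
        c(donor = lig_h$parent[i], hydrogen = lig_h$id[i], acceptor = acc)
    }
  }
  # ligand accepts: partner donor + its hydrogen vs ligand O (donor or acceptor role)
  par_h <- par[par$role == "hydrogen" & par$parent %in% par$id[par$role == "donor"], ,
               drop = FALSE]
  for (acc in lig$id[lig$role %in% c("acceptor", "donor")]) {
    for (i in seq_len(nrow(par_h))) {
      triples[[length(triples) + 1L]] <-
        c(donor = par_h$parent[i], hydrogen = par_h$id[i], acceptor = acc)
    }
  }
  triples
}

#' Is the ligand hydrogen bonded to the site in one frame?
#'
#' Tests every candidate (donor, hydrogen, acceptor) triple between the
#' ligand group and the site partner atoms, in both directions (ligand
#' hydroxyl as donor to site acceptors, and as acceptor from site donors),
#' and reports whether at least one satisfies the criterion.
#'
#' @param traj A `toy_trajectory`.
#' @param frame Frame index (1-based).
#' @param ligand_ids,partner_ids Atom id vectors; default to the
#'   trajectory's ligand and site groups.
#' @param criterion An [hbond_criterion()].
#' @return Logical flag.
#' @export
frame_bonded <- function(traj, frame, ligand_ids = NULL, partner_ids = NULL,
                         criterion = hbond_criterion()) {
  b <- bonded_frames(traj, ligand_ids, partner_ids, criterion)
  b$bonded[frame]
}

bonded_frames <- function(traj, ligand_ids = NULL, partner_ids = NULL,
                          criterion = hbond_criterion()) {
  stopifnot(inherits(traj, "toy_trajectory"))
  atoms <- traj$atoms
  if (is.null(ligand_ids)) ligand_ids <- atoms$id[atoms$group == "ligand"]
  if (is.null(partner_ids)) partner_ids <- atoms$id[atoms$group == "site"]
  triples <- candidate_triples(atoms, ligand_ids, partner_ids)
  n <- n_frames(traj)
  bonded <- rep(FALSE, n)
  per_triple <- matrix(FALSE, n, length(triples))
  coord_mat <- function(id) matrix(traj$coords[, id, , drop = FALSE], ncol = 3)
  for (j in seq_along(triples)) {
    tr <- triples[[j]]
    g <- hbond_geometry(coord_mat(tr[["donor"]]),
                        coord_mat(tr[["hydrogen"]]),
                        coord_mat(tr[["acceptor"]]),
                        criterion$convention)
    hit <- g$d_da <= criterion$d_cut & g$deviation <= criterion$angle_cut
    per_triple[, j] <- hit
    bonded <- bonded | hit
  }
  list(bonded = bonded, per_triple = per_triple, triples = triples)
}

#' Hydrogen-bond occupancy of a trajectory
#'
#' Fraction of frames, after excluding an initial burn-in, in which the
#' ligand forms at least one hydrogen bond with the site (`P_hb`).
#' Deterministic for fixed input.
#'
#' @inheritParams frame_bonded
#' @param burn_in_fraction Fraction of initial frames excluded from the
#'   analysis (default 0.25, mirroring the discard of the first quarter of
#'   a production run).
#' @return An object of class `occupancy_result`: `p_hb`, `frames_used`,
#'   `frames_excluded`, and `per_partner` bonded-frame counts.
#' @export
occupancy <- function(traj, ligand_ids = NULL, partner_ids = NULL,
                      criterion = hbond_criterion(), burn_in_fraction = 0.25) {
  if (!is.finite(burn_in_fraction) || burn_in_fraction < 0 ||
      burn_in_fraction >= 1) {
    stop("`burn_in_fraction` must lie in [0, 1)")
  }
  n <- n_frames(traj)
  excl <- floor(burn_in_fraction * n)
  used <- n - excl
  if (used < 1) stop("no frames left after burn-in")
  b <- bonded_frames(traj, ligand_ids, partner_ids, criterion)
  keep <- seq.int(excl + 1L, n)
  partners <- vapply(b$triples, function(tr) {
    # the site-side atom of the triple
    ids <- c(tr[["donor"]], tr[["acceptor"]])
    ids[ids %in% traj$atoms$id[traj$atoms$group == "site"]][1]
  }, character(1))
  counts <- tapply(colSums(b$per_triple[keep, , drop = FALSE]), partners, sum)
  structure(
    list(p_hb = mean(b$bonded[keep]), frames_used = used,
         frames_excluded = excl,
         per_partner = counts),
    class = "occupancy_result"
  )
}

#' @export
print.occupancy_result <- function(x, ...) {
  cat(sprintf("occupancy_result: P_hb = %.3f (%d frames used, %d excluded)\n",
              x$p_hb, x$frames_used, x$frames_excluded))
  invisible(x)
}

#' Classify a site by hydrogen-bond probability
#'
#' Sites with `P_hb > high_threshold` are "high" (persistent hydrogen
#' bonding), sites with `P_hb < low_threshold` are "low", anything between
#' is "intermediate". The default thresholds (0.8 and 0.3) separate the
#' high-affinity from the low-affinity interfaces in the selectivity
#' analysis.
#'
#' @param p_hb Hydrogen-bond probability in `[0, 1]` (vectorized).
#' @param high_threshold,low_threshold Classification cutoffs.
#' @return Character vector in `{"high", "intermediate", "low"}`.
#' @export
classify_site_by_phb <- function(p_hb, high_threshold = 0.8,
                                 low_threshold = 0.3) {
  if (any(!is.finite(p_hb) | p_hb < 0 | p_hb > 1)) {
    stop("`p_hb` must lie in [0, 1]")
  }
  ifelse(p_hb > high_threshold, "high",
         ifelse(p_hb < low_threshold, "low", "intermediate"))
}
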