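# Shared fixtures and independent oracles used across the suite.

# Build a toy_trajectory directly from an atom roster and a list of
# per-frame coordinate matrices (n_atoms x 3), bypassing the sampler.
make_trajectory <- function(atoms, frames, lambda = 1, seed = 0L) {
  coords <- array(NA_real_, dim = c(length(frames), nrow(atoms), 3),
                  dimnames = list(NULL, atoms$id, c("x", "y", "z")))
  for (f in seq_along(frames)) coords[f, , ] <- frames[[f]]
  structure(
    list(atoms = atoms, coords = coords, u_site = NULL, accept_rate = NA,
         frame_interval = 1, lambda = lambda, seed = seed),
    class = "toy_trajectory")
}

# Minimal ligand + one site acceptor roster.
ligand_acceptor_atoms <- function() {
  data.frame(
    id = c("O1", "H1", "C1", "SA1"),
    role = c("donor", "hydrogen", "other", "acceptor"),
    parent = c(NA, "O1", NA, NA),
    group = c("ligand", "ligand", "ligand", "site"),
    stringsAsFactors = FALSE)
}

# A frame where the ligand donates a textbook-collinear hydrogen bond to
# the acceptor (d_OA = 2.9 A, deviation 0), shifted by `offset`.
bonded_frame <- function(offset = c(0, 0, 0)) {
  rbind(O1 = c(0, 0, 0), H1 = c(1, 0, 0), C1 = c(-0.5, 1.3, 0),
        SA1 = c(2.9, 0, 0)) + rep(offset, each = 4)
}

# A frame with the acceptor far away (never bonded).
unbonded_frame <- function() {
  rbind(O1 = c(0, 0, 0), H1 = c(1, 0, 0), C1 = c(-0.5, 1.3, 0),
        SA1 = c(8, 8, 8))
}

# Exhaustive-enumeration hydrogen-bond occupancy oracle, written with its
# own vector arithmetic and triple enumeration (independent of the
# package's vectorized path).
oracle_phb <- function(traj, d_cut = 3.3, angle_cut = 40,
                       burn_in_fraction = 0.25) {
  atoms <- traj$atoms
  n <- dim(traj$coords)[1]
  excl <- floor(burn_in_fraction * n)
  lig <- atoms[atoms$group == "ligand", ]
  site <- atoms[atoms$group == "site", ]
  angle_deg <- function(v1, v2) {
    acos(min(1, max(-1, sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
  }
  triple_ok <- function(D, H, A) {
    sqrt(sum((A - D)^2)) <= d_cut && angle_deg(H - D, A - D) <= angle_cut
  }
  bonded <- logical(n)
  for (f in seq_len(n)) {
    co <- traj$coords[f, , ]
    hit <- FALSE
    for (hi in which(lig$role == "hydrogen")) {
      for (ai in which(site$role == "acceptor")) {
        if (triple_ok(co[lig$parent[hi], ], co[lig$id[hi], ], co[site$id[ai], ]))
          hit <- TRUE
      }
    }
    for (hi in which(site$role == "hydrogen")) {
      for (ai in which(lig$role %in% c("donor", "acceptor"))) {
        if (triple_ok(co[site$parent[hi], ], co[site$id[hi], ], co[lig$id[ai], ]))
          hit <- TRUE
      }
    }
    bonded[f] <- hit
  }
  mean(bonded[seq.int(excl + 1, n)])
}

# Closed-form normal-equations OLS oracle for y = a x + b.
oracle_ols <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  res <- y - X %*% beta
  s2 <- sum(res^2) / (length(y) - 2)
  covb <- s2 * solve(t(X) %*% X)
  list(b = beta[1], a = beta[2], se_b = sqrt(covb[1, 1]),
       se_a = sqrt(covb[2, 2]),
       r2 = 1 - sum(res^2) / sum((y - mean(y))^2))
}

# Batch-means standard error for autocorrelated Monte Carlo series.
batch_se <- function(x, n_batch = 50) {
  m <- floor(length(x) / n_batch)
  bm <- colMeans(matrix(x[seq_len(m * n_batch)], nrow = m))
  stats::sd(bm) / sqrt(n_batch)
}

# Random rigid motion (rotation + translation) applied to every atom of
# every frame of a trajectory.
apply_rigid_motion <- function(traj, seed = 1) {
  set.seed(seed)
  ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
  th <- stats::runif(1, 0, 2 * pi)
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3, 3,
              byrow = TRUE)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
  shift <- stats::runif(3, -5, 5)
  out <- traj
  for (f in seq_len(dim(traj$coords)[1])) {
    out$coords[f, , ] <- t(R %*% t(traj$coords[f, , ])) +
      rep(shift, each = dim(traj$coords)[2])
  }
  out
}
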