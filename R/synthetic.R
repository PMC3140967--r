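# Synthetic fixtures with analytic ground truth: hinge proteins with open
# and closed conformers, dwell/transition trajectories, and Gaussian
# ensembles drawn from a known covariance.
#
# The hinge protein emulates a two-lobe kinase-domain geometry: two compact
# CA-bead domains (solenoid coils with exact 3.8 A consecutive spacing)
# joined by a 2-residue hinge; open and closed states differ only by a
# rigid rotation of domain 2 about the hinge axis.

# place atom D from atoms A,B,C with bond length r, bond angle theta
# (B-C-D, degrees) and torsion phi (A-B-C-D, degrees): NeRF construction
nerf_place <- function(A, B, C, r, theta, phi) {
  th <- theta * pi / 180; ph <- phi * pi / 180
  bc <- C - B; bc <- bc / sqrt(sum(bc^2))
  ab <- B - A
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d_local <- c(-r * cos(th), r * sin(th) * cos(ph), r * sin(th) * sin(ph))
  C + d_local[1] * bc + d_local[2] * m + d_local[3] * n
}

#' Build an ideal N-CA-C backbone from phi/psi angles
#'
#' Internal-coordinate (NeRF) construction with ideal bond lengths
#' (N-CA 1.458, CA-C 1.525, C-N 1.329 A), ideal angles (N-CA-C 111.2,
#' CA-C-N 116.2, C-N-CA 121.7 deg) and trans peptide bonds (omega 180).
#' `phi[1]` and `psi[n]` are undefined and ignored.
#'
#' @param phi,psi numeric vectors of equal length (degrees); scalars are
#'   recycled.
#' @param chain chain id (default "A").
#' @return Structure with 3 backbone atoms per residue.
#' @export
make_backbone <- function(phi, psi, chain = "A") {
  n <- max(length(phi), length(psi))
  phi <- rep_len(phi, n); psi <- rep_len(psi, n)
  .assert(n >= 2, "need at least 2 residues")
  coords <- matrix(NA_real_, 3 * n, 3)
  # residue 1 placed in the xy-plane
  coords[1, ] <- c(0, 0, 0)                       # N1
  coords[2, ] <- c(1.458, 0, 0)                   # CA1
  th <- 111.2 * pi / 180
  coords[3, ] <- coords[2, ] + 1.525 * c(cos(pi - th), sin(pi - th), 0)  # C1
  for (i in seq_len(n - 1)) {
    iN <- 3 * i - 2; iCA <- 3 * i - 1; iC <- 3 * i
    Nn <- nerf_place(coords[iN, ], coords[iCA, ], coords[iC, ],
                     1.329, 116.2, psi[i])
    CAn <- nerf_place(coords[iCA, ], coords[iC, ], Nn, 1.458, 121.7, 180)
    Cn <- nerf_place(coords[iC, ], Nn, CAn, 1.525, 111.2, phi[i + 1])
    coords[3 * i + 1, ] <- Nn
    coords[3 * i + 2, ] <- CAn
    coords[3 * i + 3, ] <- Cn
  }
  atoms <- data.frame(
    name = rep(c("N", "CA", "C"), n),
    element = rep(c("N", "C", "C"), n),
    resid = rep(seq_len(n), each = 3),
    icode = "",
    resname = "ALA",
    chain = chain)
  new_structure(atoms, coords)
}

# solenoid CA trace: helix of radius `radius` with consecutive CA-CA
# distance exactly `spacing`, axis along +x, starting at `origin`
solenoid_ca <- function(n, origin = c(0, 0, 0), radius = 7, rise = 1.0,
                        spacing = 3.8) {
  chord <- sqrt(spacing^2 - rise^2)
  dphi <- 2 * asin(chord / (2 * radius))
  k <- seq_len(n) - 1
  xyz <- cbind(k * rise, radius * cos(k * dphi), radius * sin(k * dphi))
  sweep(xyz, 2, xyz[1, ] - origin, `-`)   # first CA sits at `origin`
}

#' Generate a two-domain hinge protein in its open or closed state
#'
#' Two compact CA-bead solenoid domains joined by a 2-residue hinge along
#' the x axis. The closed state is the open state with every domain-2 atom
#' rigidly rotated about the z axis through the last hinge CA, by the
#' difference of the two hinge angles; domain 1 and the hinge are
#' bit-identical across states. Consecutive CA-CA distances are 3.8 A by
#' construction (deviations < 0.01 A at the three junctions).
#'
#' @param n_res integer pair: residues per domain (default `c(30, 30)`,
#'   each >= 10).
#' @param open_angle,closed_angle interdomain (hinge) angles in degrees
#'   (defaults 120 and 60; must differ by >= 10).
#' @param state `"open"` or `"closed"`.
#' @param backbone `"ca"` (default) for CA beads, `"full"` to decorate each
#'   residue with N and C atoms for SASA/dihedral work.
#' @return Structure; attribute `domains` gives the residue intervals of
#'   domain 1, hinge, and domain 2.
#' @export
make_hinge_protein <- function(n_res = c(30, 30), open_angle = 120,
                               closed_angle = 60,
                               state = c("open", "closed"),
                               backbone = c("ca", "full")) {
  state <- match.arg(state)
  backbone <- match.arg(backbone)
  .assert(length(n_res) == 2 && all(n_res >= 10),
          "need at least 10 residues per domain")
  .assert(abs(open_angle - closed_angle) >= 10,
          "open and closed hinge angles must differ by at least 10 degrees")
  n1 <- n_res[1]; n2 <- n_res[2]
  d1 <- solenoid_ca(n1)
  # 2-residue hinge continuing along +x from the domain-1 end
  h1 <- d1[n1, ] + c(3.8, 0, 0)
  h2 <- h1 + c(3.8, 0, 0)
  d2 <- solenoid_ca(n2, origin = h2 + c(3.8, 0, 0))
  ca <- rbind(d1, h1, h2, d2)
  # state geometry: rotate domain 2 about z through the last hinge CA
  angle <- if (state == "open") 180 - open_angle else 180 - closed_angle
  R <- rotation_matrix(c(0, 0, 1), angle)
  i2 <- (n1 + 3):(n1 + 2 + n2)
  ca[i2, ] <- sweep(sweep(ca[i2, , drop = FALSE], 2, h2) %*% t(R), 2, h2, `+`)
  nres_tot <- n1 + 2 + n2
  if (backbone == "ca") {
    atoms <- data.frame(name = "CA", element = "C",
                        resid = seq_len(nres_tot), icode = "",
                        resname = "ALA", chain = "A")
    s <- new_structure(atoms, ca)
  } else {
    coords <- matrix(NA_real_, 3 * nres_tot, 3)
    for (i in seq_len(nres_tot)) {
      prev <- ca[max(i - 1, 1), ]; nxt <- ca[min(i + 1, nres_tot), ]
      tp <- prev - ca[i, ]; tn <- nxt - ca[i, ]
      if (i == 1) tp <- -tn
      if (i == nres_tot) tn <- -tp
      up <- c(0, 0, 1)
      coords[3 * i - 2, ] <- ca[i, ] + 1.458 * normalize3(tp + 0.5 * up)
      coords[3 * i - 1, ] <- ca[i, ]
      coords[3 * i, ] <- ca[i, ] + 1.525 * normalize3(tn + 0.5 * up)
    }
    atoms <- data.frame(
      name = rep(c("N", "CA", "C"), nres_tot),
      element = rep(c("N", "C", "C"), nres_tot),
      resid = rep(seq_len(nres_tot), each = 3),
      icode = "", resname = "ALA", chain = "A")
    s <- new_structure(atoms, coords)
  }
  attr(s, "domains") <- list(domain1 = c(1, n1), hinge = c(n1 + 1, n1 + 2),
                             domain2 = c(n1 + 3, nres_tot))
  s
}

normalize3 <- function(v) v / sqrt(sum(v^2))

#' Synthetic dwell or single-switch trajectory between two conformers
#'
#' Frames before `switch_frame` jitter around the open structure; from
#' `switch_frame` the coordinates interpolate linearly to the closed
#' structure over 10 frames and then jitter around it. `switch_frame = NULL`
#' gives a pure dwell in the open state. Noise is isotropic Gaussian per
#' coordinate (a stand-in for thermal fluctuation, not a thermostat).
#'
#' @param open,closed Structures sharing atom count and ordering.
#' @param n_frames number of frames.
#' @param switch_frame frame index at which the transition starts, or
#'   `NULL` for no transition.
#' @param noise_sigma coordinate noise standard deviation in Angstrom
#'   (default 0.3).
#' @param seed RNG seed (required: generators are bit-reproducible).
#' @param dt frame spacing in ps (default 10).
#' @return Trajectory with the open structure as topology.
#' @export
make_transition_trajectory <- function(open, closed, n_frames = 200,
                                       switch_frame = NULL,
                                       noise_sigma = 0.3, seed = 1,
                                       dt = 10) {
  .assert(n_atoms(open) == n_atoms(closed),
          "open and closed structures must share topology")
  if (!is.null(switch_frame)) {
    .assert(switch_frame >= 1 && switch_frame <= n_frames,
            "switch_frame %d outside 1..%d", switch_frame, n_frames)
  }
  n <- n_atoms(open)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  ramp_len <- 10
  frames <- vapply(seq_len(n_frames), function(k) {
    base <- if (is.null(switch_frame) || k < switch_frame) {
      open$coords
    } else if (k >= switch_frame + ramp_len - 1) {
      closed$coords
    } else {
      w <- (k - switch_frame + 1) / (ramp_len - 1)
      (1 - w) * open$coords + w * closed$coords
    }
    base + matrix(stats::rnorm(3 * n, sd = noise_sigma), n, 3)
  }, matrix(0, n, 3))
  new_trajectory(array(frames, dim = c(n, 3, n_frames)),
                 times = (seq_len(n_frames) - 1) * dt, topology = open)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Gaussian ensemble with known covariance (analytic entropy truth)
#'
#' Draws i.i.d. multivariate-normal frames about the mean structure. The
#' generator covariance is stored in the `generator_covariance` attribute
#' so estimators can be checked against the analytic value.
#'
#' @param mean Structure providing the mean coordinates and topology.
#' @param covariance 3N x 3N positive semidefinite matrix (Angstrom^2),
#'   coordinate order (x1, y1, z1, x2, ...).
#' @param n_frames number of frames.
#' @param seed RNG seed.
#' @param dt frame spacing in ps (default 1).
#' @return Trajectory; attribute `generator_covariance` is the input matrix.
#' @export
sample_gaussian_ensemble <- function(mean, covariance, n_frames = 1000,
                                     seed = 1, dt = 1) {
  n3 <- 3 * n_atoms(mean)
  covariance <- as.matrix(covariance)
  .assert(all(dim(covariance) == n3),
          "covariance must be %d x %d", n3, n3)
  e <- eigen((covariance + t(covariance)) / 2, symmetric = TRUE)
  .assert(min(e$values) >= -1e-8 * max(abs(e$values), 1e-300),
          "covariance is not positive semidefinite")
  lam <- pmax(e$values, 0)
  L <- e$vectors %*% (sqrt(lam) * t(e$vectors))   # symmetric square root
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  mu <- as.numeric(t(mean$coords))                # atom-major (x,y,z)
  Z <- matrix(stats::rnorm(n_frames * n3), n_frames, n3)
  X <- sweep(Z %*% L, 2, mu, `+`)
  frames <- array(0, dim = c(n_atoms(mean), 3, n_frames))
  for (k in seq_len(n_frames)) {
    frames[, , k] <- matrix(X[k, ], ncol = 3, byrow = TRUE)
  }
  traj <- new_trajectory(frames, times = (seq_len(n_frames) - 1) * dt,
                         topology = mean)
  attr(traj, "generator_covariance") <- covariance
  traj
}

#' Covariance implied by an elastic network's internal modes
#'
#' Pseudo-inverse over the internal (non-rigid) modes,
#' `sigma = scale * sum_k v_k v_k^T / lambda_k`: the thermal covariance of
#' the harmonic network up to the overall scale. Useful as an analytic
#' ground truth for Schlitter-entropy tests because it contains no
#' rigid-body component.
#'
#' @param modes an `inm_modes` with all internal modes retained.
#' @param scale overall variance scale (Angstrom^2 x lambda units).
#' @return 3N x 3N covariance matrix.
#' @export
enm_covariance <- function(modes, scale = 1) {
  V <- modes$vectors
  scale * (V %*% ((1 / modes$values) * t(V)))
}
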