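# Shrake-Rupley solvent accessible surface area.
#
# Per atom: quasi-uniform points are placed on the sphere of radius
# r_atom + probe; the accessible fraction (points not inside any neighbor's
# expanded sphere) times 4 pi (r + probe)^2 is the atom's SASA.

#' Default van der Waals radii (Angstrom) used for SASA
#' @return named numeric vector of per-element radii.
#' @export
default_sasa_radii <- function() {
  c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20, P = 1.80, SE = 1.90)
}

# deterministic quasi-uniform sphere points (golden-spiral / Fibonacci)
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Per-atom solvent accessible surface area (Shrake-Rupley)
#'
#' @param structure Structure (or bare N x 3 coordinates together with
#'   `elements`).
#' @param radii named per-element radii in Angstrom
#'   (default [default_sasa_radii()]).
#' @param probe solvent probe radius in Angstrom (default 1.4, water).
#' @param n_points sphere sample points per atom (default 960).
#' @param elements element vector when `structure` is a bare matrix.
#' @return numeric vector of per-atom SASA in Angstrom^2.
#' @export
sasa <- function(structure, radii = default_sasa_radii(), probe = 1.4,
                 n_points = 960, elements = NULL) {
  if (inherits(structure, "inm_structure")) {
    xyz <- structure$coords
    elements <- structure$atoms$element
  } else {
    xyz <- as.matrix(structure)
    .assert(!is.null(elements), "bare coordinates need an elements vector")
  }
  .assert(n_points >= 100, "n_points must be at least 100")
  el <- toupper(elements)
  unknown <- setdiff(unique(el), names(radii))
  .assert(length(unknown) == 0, "no SASA radius for element(s): %s",
          paste(unknown, collapse = ", "))
  r <- unname(radii[el]) + probe
  n <- nrow(xyz)
  pts <- sphere_points(n_points)
  out <- numeric(n)
  d2 <- as.matrix(stats::dist(xyz))^2
  for (i in seq_len(n)) {
    nb <- which(d2[i, ] < (r[i] + r)^2 & seq_len(n) != i)
    if (!length(nb)) {
      out[i] <- 4 * pi * r[i]^2
      next
    }
    p <- sweep(pts * r[i], 2, xyz[i, ], `+`)       # n_points x 3
    buried <- rep(FALSE, n_points)
    for (j in nb) {
      dj <- sweep(p, 2, xyz[j, ])
      buried <- buried | (rowSums(dj^2) < r[j]^2)
      if (all(buried)) break
    }
    out[i] <- 4 * pi * r[i]^2 * mean(!buried)
  }
  out
}

#' Per-residue SASA profile over a trajectory
#'
#' Atom SASA is computed on the full structure each frame (exposure depends
#' on all atoms), then summed per residue of the requested region. The
#' spread over frames is the population standard deviation, so duplicated
#' frames leave both mean and std unchanged.
#'
#' @param traj Trajectory.
#' @param region inclusive residue interval `c(lo, hi)` (or list of
#'   intervals) to report; `NULL` for all residues.
#' @param probe probe radius in Angstrom (default 1.4).
#' @param radii per-element radii (default [default_sasa_radii()]).
#' @param n_points sphere points per atom (default 960).
#' @return data.frame with columns `resid`, `mean_sasa`, `sd_sasa`
#'   (Angstrom^2); attributes `probe`, `n_points`.
#' @export
sasa_profile <- function(traj, region = NULL, probe = 1.4,
                         radii = default_sasa_radii(), n_points = 960) {
  topo <- traj$topology
  resids <- topo$atoms$resid
  keep_res <- sort(unique(resids))
  if (!is.null(region)) {
    if (is.numeric(region)) region <- list(region)
    inside <- rep(FALSE, length(keep_res))
    for (iv in region) inside <- inside | (keep_res >= iv[1] &
                                             keep_res <= iv[2])
    keep_res <- keep_res[inside]
    .assert(length(keep_res) > 0, "region resolves no residues")
  }
  nf <- n_frames(traj)
  per_frame <- vapply(seq_len(nf), function(k) {
    a <- sasa(frame_coords(traj, k), radii = radii, probe = probe,
              n_points = n_points, elements = topo$atoms$element)
    vapply(keep_res, function(rr) sum(a[resids == rr]), numeric(1))
  }, numeric(length(keep_res)))
  per_frame <- matrix(per_frame, nrow = length(keep_res))
  out <- data.frame(
    resid = keep_res,
    mean_sasa = rowMeans(per_frame),
    sd_sasa = apply(per_frame, 1, pop_sd))
  attr(out, "probe") <- probe
  attr(out, "n_points") <- n_points
  out
}
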