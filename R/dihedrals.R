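# Backbone phi/psi dihedral angles and their 2-D densities.

#' Torsion angle defined by four points
#'
#' IUPAC sign convention; result in degrees in the interval (-180, 180].
#'
#' @param p1,p2,p3,p4 length-3 coordinate vectors.
#' @return angle in degrees.
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  cross <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                            a[3] * b[1] - a[1] * b[3],
                            a[1] * b[2] - a[2] * b[1])
  n1 <- cross(b1, b2); n2 <- cross(b2, b3)
  # sign: (n1 x n2) . b2hat, the right-hand rule looking down the b2 bond
  m1 <- cross(b2 / sqrt(sum(b2^2)), n1)
  ang <- atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Backbone phi/psi series over a trajectory
#'
#' phi(i) is the torsion C(i-1)-N(i)-CA(i)-C(i); psi(i) is
#' N(i)-CA(i)-C(i)-N(i+1). Chain-terminal residues yield only the defined
#' angle (NA for the other); residues with missing backbone atoms are
#' omitted and listed in the `omitted` attribute.
#'
#' @param traj Trajectory whose topology carries N, CA, C atoms.
#' @param residues residue ids to evaluate; `NULL` for all.
#' @return object of class `inm_dihedrals`: list with `residues`, `phi` and
#'   `psi` (frames x residues matrices, degrees in (-180, 180]), and an
#'   `omitted` attribute naming skipped residues.
#' @export
backbone_dihedrals <- function(traj, residues = NULL) {
  topo <- traj$topology
  a <- topo$atoms
  all_res <- sort(unique(a$resid))
  if (is.null(residues)) residues <- all_res
  idx_of <- function(resid, name) {
    w <- which(a$resid == resid & a$name == name)
    if (length(w) == 1) w else NA_integer_
  }
  plan <- lapply(residues, function(r) {
    chain <- unique(a$chain[a$resid == r])
    if (length(chain) != 1) return(NULL)
    same_chain <- function(rr) rr %in% a$resid[a$chain == chain]
    iN <- idx_of(r, "N"); iCA <- idx_of(r, "CA"); iC <- idx_of(r, "C")
    if (anyNA(c(iN, iCA, iC))) return(NULL)
    iCp <- if (same_chain(r - 1)) idx_of(r - 1, "C") else NA_integer_
    iNn <- if (same_chain(r + 1)) idx_of(r + 1, "N") else NA_integer_
    list(resid = r, phi = c(iCp, iN, iCA, iC), psi = c(iN, iCA, iC, iNn))
  })
  ok <- !vapply(plan, is.null, logical(1))
  omitted <- residues[!ok]
  plan <- plan[ok]
  .assert(length(plan) > 0, "no residue has complete N/CA/C backbone atoms")
  nf <- n_frames(traj)
  res_ok <- vapply(plan, `[[`, numeric(1), "resid")
  phi <- psi <- matrix(NA_real_, nf, length(plan),
                       dimnames = list(NULL, res_ok))
  for (k in seq_len(nf)) {
    xyz <- frame_coords(traj, k)
    for (q in seq_along(plan)) {
      ip <- plan[[q]]$phi; is_ <- plan[[q]]$psi
      if (!anyNA(ip)) phi[k, q] <- dihedral_angle(xyz[ip[1], ], xyz[ip[2], ],
                                                  xyz[ip[3], ], xyz[ip[4], ])
      if (!anyNA(is_)) psi[k, q] <- dihedral_angle(xyz[is_[1], ],
                                                   xyz[is_[2], ],
                                                   xyz[is_[3], ],
                                                   xyz[is_[4], ])
    }
  }
  structure(list(residues = res_ok, phi = phi, psi = psi),
            class = "inm_dihedrals", omitted = omitted)
}

#' Normalized 2-D phi/psi histogram per residue
#'
#' Bins the (phi, psi) samples of each residue on a `bins x bins` grid over
#' (-180, 180] x (-180, 180]. The domain covers the full torus, so
#' wrap-around values land in the first/last bins and nothing is dropped;
#' each residue's histogram sums to 1 (over frames where both angles are
#' defined).
#'
#' @param series an `inm_dihedrals`.
#' @param bins grid size per axis (default 72, i.e. 5-degree bins).
#' @return named list (one residue per element) of `bins x bins` matrices;
#'   attribute `breaks` gives the common bin edges.
#' @export
dihedral_density <- function(series, bins = 72) {
  breaks <- seq(-180, 180, length.out = bins + 1)
  bin_of <- function(x) pmin(pmax(ceiling((x + 180) / (360 / bins)), 1L), bins)
  out <- lapply(seq_along(series$residues), function(q) {
    ph <- series$phi[, q]; ps <- series$psi[, q]
    ok <- !is.na(ph) & !is.na(ps)
    h <- matrix(0, bins, bins)
    if (any(ok)) {
      idx <- cbind(bin_of(ph[ok]), bin_of(ps[ok]))
      for (r in seq_len(nrow(idx))) {
        h[idx[r, 1], idx[r, 2]] <- h[idx[r, 1], idx[r, 2]] + 1
      }
      h <- h / sum(h)
    }
    h
  })
  names(out) <- series$residues
  attr(out, "breaks") <- breaks
  out
}
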