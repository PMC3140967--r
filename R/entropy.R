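# Schlitter quasi-harmonic configurational entropy from aligned ensembles.
#
#   S_conf = (kB / 2) * ln det( 1 + (kB T e^2 / hbar^2) M sigma )
#
# with M the 3N diagonal mass matrix (each atomic mass occupying three
# consecutive positions) and sigma the positional fluctuation covariance of
# the aligned ensemble. Computed in the symmetrized form
# det(1 + a M^{1/2} sigma M^{1/2}) for numerical stability. The result is an
# upper bound on the true configurational entropy.

#' Positional covariance model of an aligned ensemble
#'
#' Frames are superposed to remove overall rotation/translation: first onto
#' the first frame, then the mean structure is formed and every original
#' frame is re-superposed onto the mean (one re-iteration). The covariance
#' uses the 1/n normalization of the quasi-harmonic convention.
#'
#' @param traj Trajectory.
#' @param residue_range inclusive residue interval(s) selecting the region,
#'   or `NULL` for all residues.
#' @param atom_names atoms entering the covariance (default backbone
#'   `c("N","CA","C")`).
#' @param temperature temperature in K stored with the model (default 300).
#' @param align superpose frames before accumulating (default `TRUE`); turn
#'   off only for ensembles that are already free of rigid-body motion.
#' @return object of class `inm_covariance`: `mean_coords` (N x 3),
#'   `sigma` (3N x 3N, Angstrom^2), `masses3` (3N, amu), `temperature`,
#'   `n_frames`.
#' @export
build_covariance <- function(traj, residue_range = NULL,
                             atom_names = c("N", "CA", "C"),
                             temperature = 300, align = TRUE) {
  .assert(n_frames(traj) >= 2, "need at least 2 frames for a covariance")
  topo <- traj$topology
  sel <- if (is.null(residue_range)) {
    which(topo$atoms$name %in% atom_names)
  } else {
    sub <- select_atoms(topo, residue_range, atom_names)
    match(with(sub$atoms, paste(chain, resid, icode, name)),
          with(topo$atoms, paste(chain, resid, icode, name)))
  }
  .assert(length(sel) >= 1, "selection resolves no atoms")
  nf <- n_frames(traj)
  X <- t(vapply(seq_len(nf), function(k) {
    as.numeric(t(frame_coords(traj, k)[sel, , drop = FALSE]))
  }, numeric(3 * length(sel))))            # frames x 3N, atom-major (x,y,z)
  as_frames <- function(M) lapply(seq_len(nrow(M)), function(k) {
    matrix(M[k, ], ncol = 3, byrow = TRUE)
  })
  if (align && length(sel) >= 3) {
    fr <- as_frames(X)
    fr1 <- lapply(fr, function(f) superpose(fr[[1]], f)$transform(f))
    mean1 <- Reduce(`+`, fr1) / nf
    fr2 <- lapply(fr, function(f) superpose(mean1, f)$transform(f))
    X <- t(vapply(fr2, function(f) as.numeric(t(f)), numeric(3 * length(sel))))
  }
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  sigma <- crossprod(Xc) / nf              # 1/n normalization
  structure(list(
    mean_coords = matrix(mu, ncol = 3, byrow = TRUE),
    sigma = sigma,
    masses3 = rep(topo$masses[sel], each = 3),
    temperature = temperature,
    n_frames = nf,
    atom_count = length(sel)),
    class = "inm_covariance")
}

# log-determinant entropy core: sigma in A^2, masses in amu, T in K;
# returns molar entropy in J/mol/K
schlitter_core <- function(sigma, masses3_amu, temperature) {
  ev_s <- eigen((sigma + t(sigma)) / 2, symmetric = TRUE,
                only.values = TRUE)$values
  .assert(min(ev_s) >= -1e-8 * max(abs(ev_s), 1e-300),
          "covariance is not positive semidefinite (min eig %g)", min(ev_s))
  alpha <- .const$kB * temperature * exp(1)^2 / .const$hbar^2
  m_kg <- masses3_amu * .const$amu
  s_m2 <- sigma * 1e-20
  sqrt_m <- sqrt(m_kg)
  A <- alpha * (sqrt_m * t(sqrt_m * s_m2))   # M^{1/2} sigma M^{1/2}
  ev <- eigen((A + t(A)) / 2 + diag(nrow(A)), symmetric = TRUE,
              only.values = TRUE)$values
  ev <- pmax(ev, 1)                          # 1 + PSD term never below 1
  0.5 * .const$kB * .const$NA_ * sum(log(ev))
}

#' Schlitter configurational entropy of a covariance model
#'
#' @param cov an `inm_covariance` from [build_covariance()], or a bare
#'   3N x 3N covariance matrix in Angstrom^2 (then `masses3` and
#'   `temperature` must be given).
#' @param units `"J/mol/K"` (default) or `"kJ/mol/K"`.
#' @param masses3,temperature only for the bare-matrix form: 3N masses in
#'   amu and temperature in K.
#' @return total configurational entropy (nonnegative) in the chosen units.
#' @export
schlitter_entropy <- function(cov, units = c("J/mol/K", "kJ/mol/K"),
                              masses3 = NULL, temperature = NULL) {
  units <- match.arg(units)
  if (inherits(cov, "inm_covariance")) {
    s <- schlitter_core(cov$sigma, cov$masses3, cov$temperature)
  } else {
    .assert(!is.null(masses3) && !is.null(temperature),
            "bare covariance matrix needs masses3 and temperature")
    s <- schlitter_core(as.matrix(cov), masses3, temperature)
  }
  if (units == "kJ/mol/K") s / 1000 else s
}

#' Per-region per-atom backbone configurational entropy with block errors
#'
#' For each named region: the Schlitter entropy of the backbone (N, CA, C)
#' atoms over the full ensemble divided by the atom count, plus the standard
#' deviation of the same per-atom value over `n_blocks` contiguous
#' equal-length frame blocks.
#'
#' @param traj Trajectory.
#' @param regions named list; each element a `c(lo, hi)` interval or list of
#'   intervals (author residue numbering).
#' @param n_blocks number of contiguous blocks for the error bar
#'   (default 3, minimum 2).
#' @param temperature K (default 300).
#' @param units `"J/mol/K"` (default) or `"kJ/mol/K"` per atom.
#' @param atom_names backbone atom set (default `c("N","CA","C")`).
#' @return data.frame with columns `region`, `residues`, `n_atoms`,
#'   `entropy_per_atom`, `block_sd`, `n_blocks`.
#' @export
region_entropy <- function(traj, regions, n_blocks = 3, temperature = 300,
                           units = c("J/mol/K", "kJ/mol/K"),
                           atom_names = c("N", "CA", "C")) {
  units <- match.arg(units)
  .assert(n_blocks >= 2, "need at least 2 blocks for a standard deviation")
  .assert(length(regions) >= 1 && !is.null(names(regions)),
          "regions must be a named list")
  nf <- n_frames(traj)
  .assert(nf >= 2 * n_blocks, "too few frames (%d) for %d blocks", nf, n_blocks)
  block_id <- ceiling(seq_len(nf) / (nf / n_blocks))
  out <- lapply(names(regions), function(nm) {
    iv <- regions[[nm]]
    if (is.numeric(iv)) iv <- list(iv)
    per_atom <- function(sub_traj) {
      cm <- build_covariance(sub_traj, residue_range = iv,
                             atom_names = atom_names,
                             temperature = temperature)
      schlitter_entropy(cm, units = units) / cm$atom_count
    }
    full <- per_atom(traj)
    blocks <- vapply(seq_len(n_blocks), function(b) {
      k <- which(block_id == b)
      per_atom(new_trajectory(traj$coords[, , k, drop = FALSE],
                              traj$times[k], traj$topology))
    }, numeric(1))
    cm0 <- build_covariance(traj, residue_range = iv, atom_names = atom_names,
                            temperature = temperature)
    data.frame(region = nm,
               residues = paste(vapply(iv, function(x)
                 paste(x, collapse = "-"), character(1)), collapse = ","),
               n_atoms = cm0$atom_count,
               entropy_per_atom = full,
               block_sd = stats::sd(blocks),
               n_blocks = n_blocks)
  })
  out <- do.call(rbind, out)
  attr(out, "units") <- paste(units, "per atom")
  out
}
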