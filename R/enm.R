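# Tirion elastic network model: spring network, Hessian, normal modes.
#
# The potential is E = (C/2) * sum over springs (|r_ij| - |r0_ij|)^2, with a
# spring between every node pair whose reference separation is at most the
# cutoff R_c. Diagonalizing the analytic Hessian at the reference geometry
# yields eigenvalues lambda_k and mode shapes v_k; frequencies are
# omega_k = sqrt(lambda_k) in the model's arbitrary units (unit masses, C
# phenomenological) -- the unit cancels in the frequency-weighted similarity.

#' Build a Tirion elastic network from node coordinates
#'
#' Connects every pair of nodes within `cutoff` by a Hookean spring at its
#' reference length. A disconnected network is allowed but flagged with a
#' warning, since each connected component contributes its own rigid-body
#' modes.
#'
#' @param nodes N x 3 coordinates in Angstrom (N >= 2).
#' @param cutoff spring cutoff R_c in Angstrom (default 13).
#' @param spring_constant phenomenological force constant C (default 1; it
#'   scales all eigenvalues and cancels in the similarity metric).
#' @return object of class `inm_network`: `node_coords`, `springs`
#'   (matrix with columns `i`, `j`, `rest`), `cutoff`, `spring_constant`,
#'   `n_components`.
#' @export
build_network <- function(nodes, cutoff = 13, spring_constant = 1) {
  nodes <- as.matrix(nodes)
  n <- nrow(nodes)
  .assert(n >= 2, "need at least 2 nodes")
  .assert(cutoff > 0, "cutoff must be positive")
  d <- as.matrix(stats::dist(nodes))
  pairs <- which(upper.tri(d) & d <= cutoff, arr.ind = TRUE)
  ord <- order(pairs[, 1], pairs[, 2])        # row-major: by i, then j
  pairs <- pairs[ord, , drop = FALSE]
  springs <- cbind(i = pairs[, 1], j = pairs[, 2],
                   rest = d[pairs])
  comp <- connected_components(n, springs[, 1], springs[, 2])
  n_comp <- length(unique(comp))
  if (n_comp > 1) {
    warning(sprintf(
      "elastic network is disconnected (%d components); expect %d rigid modes",
      n_comp, 6 * n_comp))
  }
  structure(list(node_coords = nodes, springs = springs, cutoff = cutoff,
                 spring_constant = spring_constant, n_components = n_comp),
            class = "inm_network")
}

#' @export
print.inm_network <- function(x, ...) {
  cat(sprintf("<ElasticNetwork> %d nodes, %d springs, cutoff %g A, C = %g\n",
              nrow(x$node_coords), nrow(x$springs), x$cutoff,
              x$spring_constant))
  invisible(x)
}

#' Tirion potential energy of a configuration
#'
#' `E = (C/2) sum_springs (|r_ij| - |r0_ij|)^2`; zero at the reference
#' configuration (and any configuration restoring all spring lengths).
#'
#' @param net an `inm_network`.
#' @param coords N x 3 coordinates.
#' @return nonnegative energy (units of C x Angstrom^2).
#' @export
tirion_energy <- function(net, coords) {
  coords <- as.matrix(coords)
  .assert(all(dim(coords) == dim(net$node_coords)),
          "coords shape does not match network")
  dvec <- coords[net$springs[, 1], , drop = FALSE] -
    coords[net$springs[, 2], , drop = FALSE]
  len <- sqrt(rowSums(dvec^2))
  0.5 * net$spring_constant * sum((len - net$springs[, "rest"])^2)
}

#' Analytic Hessian of the Tirion potential at the reference geometry
#'
#' Each spring contributes the rank-one 3x3 block `C * u u^T` on the unit
#' bond vector `u`, added to both diagonal blocks and subtracted from both
#' off-diagonal blocks. The result is exactly symmetric and positive
#' semidefinite, with the rigid-body null space of the network.
#'
#' @param net an `inm_network`.
#' @return 3N x 3N symmetric matrix.
#' @export
enm_hessian <- function(net) {
  x <- net$node_coords
  n <- nrow(x)
  H <- matrix(0, 3 * n, 3 * n)
  C <- net$spring_constant
  for (k in seq_len(nrow(net$springs))) {
    i <- net$springs[k, 1]; j <- net$springs[k, 2]
    b <- x[j, ] - x[i, ]
    len <- sqrt(sum(b^2))
    .assert(len > 1e-10, "coincident nodes %d and %d share a spring", i, j)
    u <- b / len
    K <- C * tcrossprod(u)
    ii <- (3 * i - 2):(3 * i); jj <- (3 * j - 2):(3 * j)
    H[ii, ii] <- H[ii, ii] + K
    H[jj, jj] <- H[jj, jj] + K
    H[ii, jj] <- H[ii, jj] - K
    H[jj, ii] <- H[jj, ii] - K
  }
  H
}

#' Normal modes of an elastic network Hessian
#'
#' Diagonalizes the (symmetric) Hessian, discards rigid-body modes by the
#' relative threshold `lambda < rigid_tol * lambda_max`, and returns the
#' lowest `n_modes` internal modes in ascending frequency order.
#'
#' For a connected 3-D network exactly 6 rigid modes are expected; finding
#' fewer signals an assembly bug and is an error. A disconnected network
#' (pass `n_components` from the network) expects `6 * n_components`.
#'
#' @param h 3N x 3N symmetric Hessian, or an `inm_network` (the Hessian is
#'   then built internally).
#' @param n_modes number of internal modes to retain (`Inf` for all).
#' @param n_components connected-component count (default 1; taken from the
#'   network when `h` is an `inm_network`).
#' @param rigid_tol relative eigenvalue threshold for rigid modes.
#' @return object of class `inm_modes`: `values` (ascending eigenvalues),
#'   `frequencies` (`sqrt(values)`), `vectors` (3N x n orthonormal columns),
#'   `n_rigid`, `n_nodes`.
#' @export
normal_modes <- function(h, n_modes = Inf, n_components = 1,
                         rigid_tol = 1e-8) {
  if (inherits(h, "inm_network")) {
    n_components <- h$n_components
    h <- enm_hessian(h)
  }
  .assert(isSymmetric(unname(h), tol = 1e-8), "Hessian must be symmetric")
  e <- eigen((h + t(h)) / 2, symmetric = TRUE)
  vals <- rev(e$values)            # ascending
  vecs <- e$vectors[, rev(seq_len(ncol(e$vectors))), drop = FALSE]
  lam_max <- max(abs(vals))
  rigid <- vals < rigid_tol * lam_max
  n_rigid <- sum(rigid)
  expected <- 6L * n_components
  if (n_rigid < expected) {
    stop(sprintf(
      "found %d near-zero modes but connectivity implies %d: Hessian assembly bug?",
      n_rigid, expected), call. = FALSE)
  }
  if (n_rigid > expected) {
    warning(sprintf("found %d near-zero modes (expected %d)",
                    n_rigid, expected))
  }
  keep <- which(!rigid)
  if (is.finite(n_modes)) {
    .assert(length(keep) >= n_modes,
            "requested %d internal modes but only %d available",
            n_modes, length(keep))
    keep <- keep[seq_len(n_modes)]
  }
  structure(list(values = pmax(vals[keep], 0),
                 frequencies = sqrt(pmax(vals[keep], 0)),
                 vectors = vecs[, keep, drop = FALSE],
                 n_rigid = n_rigid,
                 n_nodes = nrow(h) / 3),
            class = "inm_modes")
}

#' @export
print.inm_modes <- function(x, ...) {
  cat(sprintf("<ModeSet> %d modes over %d nodes (%d rigid discarded); omega1 = %.4g\n",
              length(x$values), x$n_nodes, x$n_rigid,
              if (length(x$frequencies)) x$frequencies[1] else NA))
  invisible(x)
}

#' Serialize / restore a ModeSet as plain text
#'
#' Writes a header table of `(index, eigenvalue, frequency)` followed by the
#' eigenvector matrix, at full double precision (round-trip exact at 1e-12).
#'
#' @param modes an `inm_modes`.
#' @param path file path.
#' @return `path` (write) or an `inm_modes` (read).
#' @export
write_modes <- function(modes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# inm_modes n_modes=%d n_nodes=%d n_rigid=%d",
                     length(modes$values), modes$n_nodes, modes$n_rigid), con)
  writeLines(paste(seq_along(modes$values),
                   sprintf("%.17g", modes$values),
                   sprintf("%.17g", modes$frequencies)), con)
  utils::write.table(format(modes$vectors, digits = 17, scientific = TRUE,
                            trim = TRUE),
                     con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_modes
#' @export
read_modes <- function(path) {
  lines <- readLines(path)
  hdr <- as.integer(regmatches(lines[1],
                               gregexpr("[0-9]+", lines[1]))[[1]])
  n_modes <- hdr[1]; n_nodes <- hdr[2]; n_rigid <- hdr[3]
  tab <- do.call(rbind, lapply(strsplit(lines[2:(1 + n_modes)], " "),
                               as.numeric))
  vec_lines <- lines[(2 + n_modes):length(lines)]
  vecs <- do.call(rbind, lapply(strsplit(trimws(vec_lines), "\\s+"),
                                as.numeric))
  structure(list(values = tab[, 2], frequencies = tab[, 3],
                 vectors = vecs, n_rigid = n_rigid, n_nodes = n_nodes),
            class = "inm_modes")
}
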