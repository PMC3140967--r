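# Atom selection, residue correspondence, rigid-body superposition and RMSD.

#' Select atoms by residue interval(s) and atom name
#'
#' Intervals are inclusive on both ends and use author-assigned residue
#' numbers. An empty selection is an error, never an empty Structure.
#'
#' @param s Structure.
#' @param residue_range list of `c(lo, hi)` inclusive intervals, or a single
#'   `c(lo, hi)` vector.
#' @param atom_names character vector of atom names to keep (e.g. `"CA"`,
#'   `c("N","CA","C")`), or `NULL` for all.
#' @return Structure containing the selected atoms in original order.
#' @export
select_atoms <- function(s, residue_range, atom_names = NULL) {
  if (is.numeric(residue_range)) residue_range <- list(residue_range)
  .assert(length(residue_range) >= 1, "residue_range must be nonempty")
  keep_res <- rep(FALSE, n_atoms(s))
  for (iv in residue_range) {
    .assert(length(iv) == 2 && iv[1] <= iv[2],
            "each interval must be c(lo, hi) with lo <= hi")
    keep_res <- keep_res | (s$atoms$resid >= iv[1] & s$atoms$resid <= iv[2])
  }
  keep <- keep_res
  if (!is.null(atom_names)) keep <- keep & (s$atoms$name %in% atom_names)
  if (!any(keep)) {
    stop(sprintf(
      "empty selection: requested residues %s%s, structure spans %d..%d",
      paste(vapply(residue_range, function(iv) paste(iv, collapse = "-"),
                   character(1)), collapse = ","),
      if (is.null(atom_names)) "" else
        paste0(" with atoms {", paste(atom_names, collapse = ","), "}"),
      min(s$atoms$resid), max(s$atoms$resid)), call. = FALSE)
  }
  atoms <- s$atoms[keep, , drop = FALSE]
  rownames(atoms) <- NULL
  new_structure(atoms, s$coords[keep, , drop = FALSE], s$masses[keep])
}

one_letter <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V")

residue_table <- function(s) {
  a <- s$atoms
  u <- !duplicated(paste(a$chain, a$resid, a$icode))
  data.frame(resid = a$resid[u], resname = a$resname[u],
             chain = a$chain[u], stringsAsFactors = FALSE)
}

structure_sequence <- function(s) {
  rt <- residue_table(s)
  aa <- one_letter[rt$resname]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

# global Needleman-Wunsch with linear gap penalty; returns aligned index pairs
needleman_wunsch <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  F <- matrix(0, n + 1, m + 1)
  F[, 1] <- gap * (0:n); F[1, ] <- gap * (0:m)
  for (i in seq_len(n)) {
    s_row <- ifelse(av[i] == bv, match, mismatch)
    for (j in seq_len(m)) {
      F[i + 1, j + 1] <- max(F[i, j] + s_row[j], F[i, j + 1] + gap,
                             F[i + 1, j] + gap)
    }
  }
  # traceback, preferring diagonal then up then left (deterministic ties)
  i <- n; j <- m; pairs_a <- integer(0); pairs_b <- integer(0)
  while (i > 0 && j > 0) {
    sc <- if (av[i] == bv[j]) match else mismatch
    if (F[i + 1, j + 1] == F[i, j] + sc) {
      pairs_a <- c(i, pairs_a); pairs_b <- c(j, pairs_b)
      i <- i - 1; j <- j - 1
    } else if (F[i + 1, j + 1] == F[i, j + 1] + gap) {
      i <- i - 1
    } else {
      j <- j - 1
    }
  }
  list(pairs = cbind(pairs_a, pairs_b), score = F[n + 1, m + 1])
}

#' Map residues between two homologous structures
#'
#' Produces the one-to-one ordered residue correspondence needed to compare
#' structures with different author numbering (e.g. an open reference
#' numbered 27-175 against a closed reference numbered 48-196, a constant
#' offset of 21).
#'
#' @param a,b Structures.
#' @param spec one of: a 2-column matrix/data.frame of explicit
#'   `(resid in a, resid in b)` pairs; a single number interpreted as a
#'   constant offset (residue `k` in `a` maps to `k + offset` in `b`); or the
#'   string `"align"` for the built-in global sequence alignment
#'   (match +1, mismatch -1, gap -2).
#' @return object of class `inm_mapping`: data.frame with columns
#'   `resid_a`, `resid_b` plus a `provenance` attribute
#'   (`"explicit"`, `"offset"` or `"aligned"`).
#' @export
map_residues <- function(a, b, spec = 0) {
  ra <- residue_table(a); rb <- residue_table(b)
  if (is.character(spec) && identical(spec, "align")) {
    nw <- needleman_wunsch(structure_sequence(a), structure_sequence(b))
    pairs <- data.frame(resid_a = ra$resid[nw$pairs[, 1]],
                        resid_b = rb$resid[nw$pairs[, 2]])
    prov <- "aligned"
    frac <- nrow(pairs) / min(nrow(ra), nrow(rb))
    if (frac < 0.5) {
      warning(sprintf("alignment paired only %.0f%% of residues", 100 * frac))
      prov <- sprintf("aligned (low coverage %.0f%%)", 100 * frac)
    }
  } else if (is.numeric(spec) && length(spec) == 1) {
    resid_b <- ra$resid + spec
    keep <- resid_b %in% rb$resid & ra$resid %in% ra$resid
    .assert(any(keep), "offset %g maps no residue of a into b", spec)
    pairs <- data.frame(resid_a = ra$resid[keep], resid_b = resid_b[keep])
    prov <- sprintf("offset %g", spec)
  } else {
    spec <- as.data.frame(spec)
    .assert(ncol(spec) == 2, "explicit mapping must have two columns")
    pairs <- data.frame(resid_a = as.integer(spec[[1]]),
                        resid_b = as.integer(spec[[2]]))
    missing_a <- setdiff(pairs$resid_a, ra$resid)
    missing_b <- setdiff(pairs$resid_b, rb$resid)
    .assert(length(missing_a) == 0,
            "mapping references residues absent from a: %s",
            paste(missing_a, collapse = ","))
    .assert(length(missing_b) == 0,
            "mapping references residues absent from b: %s",
            paste(missing_b, collapse = ","))
    prov <- "explicit"
  }
  .assert(!anyDuplicated(pairs$resid_a) && !anyDuplicated(pairs$resid_b),
          "mapping must be one-to-one")
  attr(pairs, "provenance") <- prov
  class(pairs) <- c("inm_mapping", "data.frame")
  pairs
}

#' Write / read a residue mapping as two-column text
#'
#' Format: `A_resid B_resid` per line, `#` comments allowed.
#'
#' @param mapping an `inm_mapping`.
#' @param path file path.
#' @return `path` (write) or an `inm_mapping` (read).
#' @export
write_mapping <- function(mapping, path) {
  hdr <- sprintf("# residue mapping (%s)", attr(mapping, "provenance") %||% "?")
  writeLines(c(hdr, sprintf("%d %d", mapping$resid_a, mapping$resid_b)), path)
  invisible(path)
}

#' @rdname write_mapping
#' @export
read_mapping <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  m <- do.call(rbind, lapply(strsplit(trimws(lines), "\\s+"), as.integer))
  pairs <- data.frame(resid_a = m[, 1], resid_b = m[, 2])
  attr(pairs, "provenance") <- "explicit"
  class(pairs) <- c("inm_mapping", "data.frame")
  pairs
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation `R` (det = +1) and translation `t` minimizing
#' the RMSD of `y` transformed onto `x`: `y %*% R + t ~ x`, rows are atoms.
#'
#' @param x,y N x 3 coordinate matrices with matching rows, N >= 3,
#'   not all collinear.
#' @return list with `rotation` (3 x 3), `translation` (length 3), `rmsd`
#'   (Angstrom), and `transform(coords)` applying the fit to new coordinates.
#' @export
superpose <- function(x, y) {
  x <- as.matrix(x); y <- as.matrix(y)
  .assert(nrow(x) == nrow(y) && ncol(x) == 3 && ncol(y) == 3,
          "x and y must be N x 3 with equal N")
  .assert(nrow(x) >= 3, "need at least 3 points to superpose")
  cx <- colMeans(x); cy <- colMeans(y)
  x0 <- sweep(x, 2, cx); y0 <- sweep(y, 2, cy)
  for (m in list(x0, y0)) {
    sv <- svd(m, nu = 0, nv = 0)$d
    .assert(sv[2] > 1e-8 * max(sv[1], 1e-300),
            "degenerate (collinear) geometry; superposition is ill-posed")
  }
  s <- svd(crossprod(y0, x0))
  d <- sign(det(s$u %*% t(s$v)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  t_vec <- cx - as.numeric(cy %*% R)
  fitted <- sweep(y %*% R, 2, t_vec, `+`)
  rmsd <- sqrt(mean(rowSums((fitted - x)^2)))
  list(rotation = R, translation = t_vec, rmsd = rmsd,
       transform = function(coords) sweep(as.matrix(coords) %*% R, 2,
                                          t_vec, `+`))
}

#' RMSD between two coordinate sets after optimal superposition
#' @param x,y N x 3 matrices.
#' @return RMSD in Angstrom.
#' @export
rmsd_fit <- function(x, y) superpose(x, y)$rmsd

# indices (rows) in structure s of atoms `node` at the given residue ids,
# in the order of resids
node_indices <- function(s, resids, node = "CA") {
  idx <- vapply(resids, function(r) {
    w <- which(s$atoms$resid == r & s$atoms$name == node)
    if (length(w) != 1) NA_integer_ else w
  }, integer(1))
  if (anyNA(idx)) {
    stop(sprintf("cannot resolve atom '%s' for residue(s): %s", node,
                 paste(resids[is.na(idx)], collapse = ",")), call. = FALSE)
  }
  idx
}

#' Per-frame superposed RMSD of a trajectory against a reference
#'
#' Only mapped nodes enter the fit: residues of the reference are paired to
#' residues of the trajectory topology through `mapping`, and atom `node`
#' (default CA) of each pair defines the point sets.
#'
#' @param traj Trajectory.
#' @param ref reference Structure.
#' @param mapping an `inm_mapping` with `resid_a` in `ref`, `resid_b` in the
#'   trajectory topology; `NULL` maps identical residue numbers (offset 0).
#' @param node atom name used as the per-residue node (default `"CA"`).
#' @return data.frame with columns `time_ps`, `rmsd`.
#' @export
rmsd_trace <- function(traj, ref, mapping = NULL, node = "CA") {
  if (is.null(mapping)) mapping <- map_residues(ref, traj$topology, 0)
  .assert(nrow(mapping) >= 3, "mapping must resolve at least 3 nodes")
  i_ref <- node_indices(ref, mapping$resid_a, node)
  i_trj <- node_indices(traj$topology, mapping$resid_b, node)
  xr <- ref$coords[i_ref, , drop = FALSE]
  r <- vapply(seq_len(n_frames(traj)), function(k) {
    rmsd_fit(xr, frame_coords(traj, k)[i_trj, , drop = FALSE])
  }, numeric(1))
  data.frame(time_ps = traj$times, rmsd = r)
}
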