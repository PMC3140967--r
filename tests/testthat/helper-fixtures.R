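# fixtures built in code: tiny PDB texts, random clouds, step traces

# one ATOM line with full control of the fixed columns
pdb_atom_line <- function(serial, name, resname, chain, resid, x, y, z,
                          element = "C", altloc = " ", icode = " ",
                          occ = 1.0) {
  nm <- if (nchar(name) < 4 && nchar(element) == 1) paste0(" ", name) else name
  sprintf("ATOM  %5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, nm, altloc, resname, chain, resid, icode, x, y, z,
          occ, 0.0, element)
}

# CA-only PDB text for a coordinate matrix
ca_pdb_text <- function(xyz, chain = "A", resid = seq_len(nrow(xyz))) {
  vapply(seq_len(nrow(xyz)), function(i) {
    pdb_atom_line(i, "CA", "ALA", chain, resid[i],
                  xyz[i, 1], xyz[i, 2], xyz[i, 3])
  }, character(1))
}

# random compact point cloud guaranteed non-collinear
random_cloud <- function(n, box = 10) {
  matrix(stats::runif(3 * n, 0, box), n, 3)
}

# a synthetic trace object stepping between state scores
step_trace <- function(n, s_open_a, s_closed_a, s_open_b = NULL,
                       s_closed_b = NULL, at = NULL) {
  so <- rep(s_open_a, n); sc <- rep(s_closed_a, n)
  if (!is.null(at)) {
    so[at:n] <- s_open_b; sc[at:n] <- s_closed_b
  }
  out <- data.frame(time_ps = seq_len(n) * 10, s_open = so, s_closed = sc)
  class(out) <- c("inm_trace", "data.frame")
  out
}

# independent torsion oracle: angle between the two bond-plane normals with
# sign from the triple product (distinct code path from dihedral_angle)
torsion_oracle <- function(p1, p2, p3, p4) {
  cr <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                         a[3] * b[1] - a[1] * b[3],
                         a[1] * b[2] - a[2] * b[1])
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cr(b1, b2); n2 <- cr(b2, b3)
  cosang <- sum(n1 * n2) / sqrt(sum(n1^2) * sum(n2^2))
  ang <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
  if (sum(cr(n1, n2) * b2) < 0) ang <- -ang
  if (ang <= -180) ang <- ang + 360
  ang
}
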