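# structures module: PDB ingestion, selection, mapping, superposition, RMSD

test_that("read_structure handles trivial, chain-filtered and malformed input", {
  one <- pdb_atom_line(1, "CA", "GLY", "A", 1, 0, 0, 0)
  s <- read_structure(one)
  expect_equal(n_atoms(s), 1)
  expect_equal(s$coords, matrix(0, 1, 3))

  # chains A and B, 3 residues; chain filter keeps only B
  txt <- c(pdb_atom_line(1, "CA", "ALA", "A", 1, 0, 0, 0),
           pdb_atom_line(2, "CA", "ALA", "A", 2, 3.8, 0, 0),
           pdb_atom_line(3, "CA", "ALA", "B", 1, 0, 5, 0))
  sb <- read_structure(txt, chain_id = "B")
  expect_equal(n_atoms(sb), 1)
  expect_equal(sb$atoms$chain, "B")
  expect_error(read_structure(txt, chain_id = "C"), "available chains: A, B")

  bad <- sub("   0.000", "   x.000", one)
  expect_error(read_structure(bad), "line 1")

  # HETATM dropped
  het <- c(one, sub("^ATOM  ", "HETATM", pdb_atom_line(2, "O", "HOH", "A",
                                                       90, 1, 1, 1, "O")))
  expect_equal(n_atoms(read_structure(het)), 1)
})

test_that("multi-model read matches a character-offset parse oracle", {
  set.seed(11)
  n_models <- 5; n_at <- 4
  blocks <- lapply(seq_len(n_models), function(m) {
    xyz <- round(random_cloud(n_at), 3)
    c(sprintf("MODEL %8d", m), ca_pdb_text(xyz), "ENDMDL")
  })
  txt <- unlist(blocks)
  s4 <- read_structure(txt, model_index = 4)
  # oracle: substr the raw lines of block 4 at the PDB column offsets
  lines4 <- grep("^ATOM", blocks[[4]], value = TRUE)
  oracle <- t(vapply(lines4, function(l) {
    as.numeric(c(substr(l, 31, 38), substr(l, 39, 46), substr(l, 47, 54)))
  }, numeric(3)))
  expect_equal(unname(s4$coords), unname(oracle), tolerance = 1e-12)
  expect_equal(s4$atoms$resid, 1:4)
  expect_error(read_structure(txt, model_index = 9), "models 1\\.\\.5")
})

test_that("structure round-trips through PDB at 3-decimal precision", {
  set.seed(3)
  s <- make_hinge_protein(c(12, 12), state = "open")
  s$coords <- s$coords + stats::runif(length(s$coords), -0.0004, 0.0004)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_structure(s, path)
  s2 <- read_structure(path)
  expect_equal(s2$coords, s$coords, tolerance = 5.1e-4)
  expect_identical(s2$atoms$resid, s$atoms$resid)
  expect_identical(s2$atoms$name, s$atoms$name)
})

test_that("altloc resolution keeps highest occupancy with ties to A", {
  txt <- c(pdb_atom_line(1, "CA", "SER", "A", 1, 0, 0, 0, altloc = "A",
                         occ = 0.4),
           pdb_atom_line(2, "CA", "SER", "A", 1, 1, 0, 0, altloc = "B",
                         occ = 0.6),
           pdb_atom_line(3, "CA", "SER", "A", 2, 0, 2, 0, altloc = "B",
                         occ = 0.5),
           pdb_atom_line(4, "CA", "SER", "A", 2, 0, 3, 0, altloc = "A",
                         occ = 0.5))
  s <- read_structure(txt)
  expect_equal(n_atoms(s), 2)
  expect_equal(s$coords[1, 1], 1)   # occupancy 0.6 wins
  expect_equal(s$coords[2, 2], 3)   # tie -> altloc A
})

test_that("select_atoms filters by inclusive intervals and errors on empty", {
  xyz <- cbind(3.8 * (1:100), 0, 0) + random_cloud(100, box = 0.1)
  s <- read_structure(ca_pdb_text(xyz))
  expect_equal(n_atoms(select_atoms(s, c(1, 100), "CA")), 100)
  # excluded interior gap mimicking removal of 4 residues
  sel <- select_atoms(s, list(c(27, 71), c(76, 175)), "CA")
  expect_equal(n_atoms(sel), length(c(27:71, 76:100)))
  expect_error(select_atoms(s, c(500, 600)), "empty selection")
  expect_error(select_atoms(s, c(500, 600)), "1\\.\\.100")
})

test_that("map_residues supports identity, offset and explicit pairs", {
  a <- read_structure(ca_pdb_text(cbind(3.8 * (1:10), 0, 1:10)))
  m0 <- map_residues(a, a, 0)
  expect_equal(nrow(m0), 10)
  expect_equal(m0$resid_a, m0$resid_b)

  # open-template numbering 27..175 against closed-template 48..196:
  # constant offset 21 pairs (27,48) first and (175,196) last
  xyz <- cbind(3.8 * seq_len(149), 0, 0)
  open_toy <- read_structure(ca_pdb_text(xyz, resid = 27:175))
  closed_toy <- read_structure(ca_pdb_text(xyz, resid = 48:196))
  m <- map_residues(open_toy, closed_toy, 21)
  expect_equal(nrow(m), 149)
  expect_equal(unlist(m[1, ]), c(resid_a = 27, resid_b = 48))
  expect_equal(unlist(m[149, ]), c(resid_a = 175, resid_b = 196))

  expect_error(map_residues(a, a, cbind(1:3, 90:92)), "absent from b")
  m2 <- map_residues(a, a, cbind(2:4, 5:7))
  expect_equal(attr(m2, "provenance"), "explicit")

  path <- withr::local_tempfile(fileext = ".map")
  write_mapping(m2, path)
  expect_equal(read_mapping(path)$resid_b, 5:7)
})

test_that("built-in aligner matches Needleman-Wunsch oracle (Biostrings)", {
  skip_if_not_installed("Biostrings")
  seq_a <- "MKTAYIAKQRQISFVK"
  seq_b <- "MKTAYIAKQISFVK"       # one internal 2-residue deletion
  helix <- function(n) cbind(1.5 * (1:n), 2.3 * cos(1.745 * (1:n)),
                             2.3 * sin(1.745 * (1:n)))
  aa3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
           E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
           M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
           Y = "TYR", V = "VAL")
  as_struct <- function(sq) {
    letters1 <- strsplit(sq, "")[[1]]
    xyz <- helix(length(letters1))
    txt <- vapply(seq_along(letters1), function(i) {
      pdb_atom_line(i, "CA", aa3[letters1[i]], "A", i,
                    xyz[i, 1], xyz[i, 2], xyz[i, 3])
    }, character(1))
    read_structure(txt)
  }
  a <- as_struct(seq_a); b <- as_struct(seq_b)
  m <- map_residues(a, b, "align")
  expect_equal(attr(m, "provenance"), "aligned")

  mat <- matrix(-1, 26, 26, dimnames = list(LETTERS, LETTERS))
  diag(mat) <- 1
  al <- Biostrings::pairwiseAlignment(seq_a, seq_b, type = "global",
                                      substitutionMatrix = mat,
                                      gapOpening = 0, gapExtension = 2)
  oracle_pairs <- sum(strsplit(as.character(Biostrings::pattern(al)),
                               "")[[1]] != "-" &
                      strsplit(as.character(Biostrings::subject(al)),
                               "")[[1]] != "-")
  expect_equal(nrow(m), oracle_pairs)
  # aligned residues must agree letter-by-letter with the oracle's matches
  expect_true(all(diff(m$resid_a) >= 1) && all(diff(m$resid_b) >= 1))
})

test_that("superpose removes rigid motions and is rotation invariant", {
  set.seed(21)
  x <- random_cloud(8)
  self <- superpose(x, x)
  expect_equal(self$rmsd, 0, tolerance = 1e-12)
  expect_equal(self$rotation, diag(3), tolerance = 1e-9)

  Rz <- rotation_matrix_z90 <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3)
  y <- sweep(x %*% Rz, 2, c(5, 0, 0), `+`)
  expect_lt(superpose(x, y)$rmsd, 1e-9)

  # invariance to pre-rotation of either cloud
  for (rep in 1:5) {
    q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
    R <- with(list(w = q[1], i = q[2], j = q[3], k = q[4]),
              matrix(c(1 - 2 * (j^2 + k^2), 2 * (i * j + w * k),
                       2 * (i * k - w * j),
                       2 * (i * j - w * k), 1 - 2 * (i^2 + k^2),
                       2 * (j * k + w * i),
                       2 * (i * k + w * j), 2 * (j * k - w * i),
                       1 - 2 * (i^2 + j^2)), 3, 3))
    y2 <- random_cloud(8)
    expect_equal(rmsd_fit(x, y2 %*% R), rmsd_fit(x, y2), tolerance = 1e-8)
  }

  expect_error(superpose(x, x[1:5, ]), "equal N")
  line <- cbind(1:5, 0, 0)
  expect_error(superpose(line, line), "degenerate")
})

test_that("superpose attains the brute-force rotational optimum", {
  set.seed(8)
  x <- random_cloud(8); y <- random_cloud(8)
  got <- superpose(x, y)$rmsd
  expect_lte(got, sqrt(mean(rowSums((x - y)^2))))
  # oracle: numerical optimization over Euler angles from several starts
  cx <- colMeans(x); cy <- colMeans(y)
  x0 <- sweep(x, 2, cx); y0 <- sweep(y, 2, cy)
  obj <- function(ang) {
    R <- rotation_matrix(c(0, 0, 1), ang[1] * 180 / pi) %*%
      rotation_matrix(c(0, 1, 0), ang[2] * 180 / pi) %*%
      rotation_matrix(c(1, 0, 0), ang[3] * 180 / pi)
    sqrt(mean(rowSums((y0 %*% R - x0)^2)))
  }
  starts <- as.matrix(expand.grid(c(0, pi), c(0, pi / 2, pi), c(0, pi)))
  oracle <- min(apply(starts, 1, function(s0) {
    stats::optim(s0, obj, method = "Nelder-Mead",
                 control = list(maxit = 2000, reltol = 1e-14))$value
  }))
  expect_equal(got, oracle, tolerance = 1e-6)
})

test_that("rmsd_trace: zeros on self, monotone on noiseless interpolation", {
  open <- make_hinge_protein(c(12, 12), state = "open")
  closed <- make_hinge_protein(c(12, 12), state = "closed")
  traj_same <- make_transition_trajectory(open, closed, n_frames = 5,
                                          switch_frame = NULL,
                                          noise_sigma = 0, seed = 1)
  tr <- rmsd_trace(traj_same, open)
  expect_equal(tr$rmsd, rep(0, 5), tolerance = 1e-9)

  # arbitrary rigid motion of the reference is removed
  R <- rotation_matrix(c(1, 2, 3), 77)
  rot <- open
  rot$coords <- sweep(open$coords %*% R, 2, c(4, -2, 9), `+`)
  expect_lt(rmsd_trace(traj_same, rot)$rmsd[1], 1e-9)

  # noiseless open->closed switch: RMSD to the open endpoint never decreases
  traj_sw <- make_transition_trajectory(open, closed, n_frames = 20,
                                        switch_frame = 5, noise_sigma = 0,
                                        seed = 1)
  r <- rmsd_trace(traj_sw, open)$rmsd
  expect_true(all(diff(r) >= -1e-9))
  expect_equal(r[1], 0, tolerance = 1e-9)
})
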