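# internal helpers shared across modules

# SI constants (CODATA 2018)
.const <- list(
  kB   = 1.380649e-23,      # J/K
  h    = 6.62607015e-34,    # J s
  hbar = 6.62607015e-34 / (2 * pi),
  amu  = 1.66053906660e-27, # kg
  NA_  = 6.02214076e23      # 1/mol
)

# standard atomic masses (amu) for elements we expect in backbone/CA models
.element_masses <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
  P = 30.974, SE = 78.971, FE = 55.845, ZN = 65.38, MG = 24.305,
  CA = 40.078, "NA" = 22.99, CL = 35.45, K = 39.098, MN = 54.938
)

`%||%` <- function(a, b) if (is.null(a)) b else a

.assert <- function(cond, msg, ...) {
  if (!isTRUE(cond)) stop(sprintf(msg, ...), call. = FALSE)
}

# proper rotation about a unit axis by angle (degrees), Rodrigues form.
rotation_matrix <- function(axis, angle_deg) {
  u <- axis / sqrt(sum(axis^2))
  a <- angle_deg * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(a) * K + (1 - cos(a)) * (K %*% K)
}

# deterministic random proper rotation (for property tests and jittered frames)
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
    2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
    2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3)
}

# nearest-integer rounding with halves away from zero (table-style percentages)
round_half_up <- function(x) floor(x + 0.5)

# union-find connected components over an edge list on n nodes
connected_components <- function(n, edges_i, edges_j) {
  edges_i <- as.integer(edges_i); edges_j <- as.integer(edges_j)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (length(edges_i)) {
    for (k in seq_along(edges_i)) {
      a <- find(edges_i[k]); b <- find(edges_j[k])
      if (a != b) parent[a] <- b
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

# population standard deviation (1/n), used where duplication invariance matters
pop_sd <- function(x) {
  m <- mean(x)
  sqrt(mean((x - m)^2))
}
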