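# INM similarity metric, trace, classification and transition tabulation

make_modeset <- function(seed, n_nodes = 12, cutoff = 8) {
  set.seed(seed)
  normal_modes(suppressWarnings(build_network(random_cloud(n_nodes, box = 9),
                                              cutoff = cutoff)))
}

test_that("match_modes recovers identity, permutations, and the brute-force table", {
  m <- make_modeset(31)
  mm <- match_modes(m, m, n = 4)
  expect_equal(mm$template, 1:4)
  expect_equal(mm$overlap, rep(1, 4), tolerance = 1e-10)

  # a permuted copy of the template is recovered with overlaps 1
  perm <- c(3, 1, 4, 2, 5:length(m$values))
  q <- m
  q$values <- m$values[perm]; q$frequencies <- m$frequencies[perm]
  q$vectors <- m$vectors[, perm]
  mm <- match_modes(q, m, n = 4)
  expect_equal(mm$template, perm[1:4])
  expect_equal(mm$overlap, rep(1, 4), tolerance = 1e-10)

  # brute-force all-pairs oracle on two different networks
  a <- make_modeset(37); b <- make_modeset(41)
  mm <- match_modes(a, b, n = 2, pool = 10)
  for (i in 1:2) {
    ovl <- vapply(1:10, function(j) abs(sum(a$vectors[, i] * b$vectors[, j])),
                  numeric(1))
    expect_equal(mm$template[i], which.max(ovl))
    expect_equal(mm$overlap[i], max(ovl), tolerance = 1e-10)
  }

  small <- make_modeset(43, n_nodes = 4, cutoff = 10)
  expect_error(match_modes(a, small), "dimensionality")
  expect_error(match_modes(a, b, n = 5, pool = 3), "pool")
})

test_that("inm_similarity equals the hand-composed weighted overlap sum", {
  a <- make_modeset(47); b <- make_modeset(53)
  s <- inm_similarity(a, b, n = 2)
  mm <- match_modes(a, b, n = 2)
  w <- b$frequencies[mm$template]
  expect_equal(s, sum(w * mm$overlap) / sum(w), tolerance = 1e-10)
  expect_equal(inm_similarity(a, a, n = 2), 1)
})

test_that("similarity is bounded, reflexive and rigid-motion invariant", {
  set.seed(59)
  for (rep in 1:5) {
    a <- make_modeset(100 + rep); b <- make_modeset(200 + rep)
    for (n in c(1, 2, 3)) {
      s <- inm_similarity(a, b, n = n)
      expect_gte(s, 0); expect_lte(s, 1)
    }
    expect_equal(inm_similarity(a, a, n = 3), 1, tolerance = 1e-10)
  }
  # documented asymmetry: both directions computed, not assumed equal
  a <- make_modeset(61); b <- make_modeset(67)
  s_ab <- inm_similarity(a, b, n = 2)
  s_ba <- inm_similarity(b, a, n = 2)
  expect_true(is.finite(s_ab) && is.finite(s_ba))

  # rigid motion of the same structure scores 1 after superposition
  open <- make_hinge_protein(c(12, 12), state = "open")
  set.seed(71)
  for (rep in 1:3) {
    R <- random_rotation()
    moved <- sweep(open$coords %*% R, 2, stats::rnorm(3, sd = 20), `+`)
    fit <- superpose(open$coords, moved)
    q <- normal_modes(build_network(fit$transform(moved)), n_modes = 2)
    t_ <- normal_modes(build_network(open$coords), n_modes = 10)
    expect_equal(inm_similarity(q, t_), 1, tolerance = 1e-8)
  }
})

test_that("similarity to the open template decays along a noiseless path", {
  # noiseless open->closed path: the hinge angle sweeps 120 -> 60 degrees
  # (domain 2 rotates rigidly, exactly the generator's state difference)
  open <- make_hinge_protein(c(15, 15), 120, 60, state = "open")
  open_modes <- normal_modes(build_network(open$coords), n_modes = 10)
  angles <- seq(120, 60, length.out = 21)
  path <- lapply(angles, function(th) {
    conf <- make_hinge_protein(c(15, 15), open_angle = th,
                               closed_angle = th - 60, state = "open")
    fit <- superpose(open$coords, conf$coords)
    q <- normal_modes(build_network(fit$transform(conf$coords)),
                      n_modes = 2)
    list(s = inm_similarity(q, open_modes),
         match = match_modes(q, open_modes)$template)
  })
  s <- vapply(path, `[[`, numeric(1), "s")
  expect_equal(s[1], 1, tolerance = 1e-10)
  expect_lt(s[21], 0.7)                       # substantial overall decay
  # nonincreasing wherever the discrete mode matching is stable; upward
  # steps can occur only where the matched template set reshuffles (the
  # documented mode-shuffling caveat of max-overlap matching)
  for (k in 1:20) {
    if (identical(path[[k]]$match, path[[k + 1]]$match)) {
      expect_lte(s[k + 1], s[k] + 1e-6)
    }
  }
})

test_that("similarity_trace equals per-frame single-shot recomputation", {
  open <- make_hinge_protein(c(12, 12), state = "open")
  closed <- make_hinge_protein(c(12, 12), state = "closed")
  traj <- make_transition_trajectory(open, closed, n_frames = 3,
                                     switch_frame = 2, noise_sigma = 0.2,
                                     seed = 5)
  tr <- similarity_trace(traj, open, closed)
  open_modes <- normal_modes(build_network(open$coords), n_modes = 10)
  closed_modes <- normal_modes(build_network(closed$coords), n_modes = 10)
  for (k in 1:3) {
    xyz <- frame_coords(traj, k)
    for (side in c("open", "closed")) {
      tmpl <- if (side == "open") open else closed
      tm <- if (side == "open") open_modes else closed_modes
      fit <- superpose(tmpl$coords, xyz)
      q <- normal_modes(build_network(fit$transform(xyz)), n_modes = 2)
      expect_equal(tr[[paste0("s_", side)]][k], inm_similarity(q, tm),
                   tolerance = 1e-9)
    }
  }
})

test_that("self-trajectory scores 1 against itself and traces round-trip", {
  open <- make_hinge_protein(c(12, 12), state = "open")
  closed <- make_hinge_protein(c(12, 12), state = "closed")
  traj <- make_transition_trajectory(open, closed, n_frames = 5,
                                     switch_frame = NULL, noise_sigma = 0,
                                     seed = 1)
  tr <- similarity_trace(traj, open, closed)
  expect_equal(tr$s_open, rep(1, 5), tolerance = 1e-9)
  expect_lt(max(tr$s_closed), 1)

  path <- withr::local_tempfile(fileext = ".tsv")
  write_trace(tr, path)
  tr2 <- read_trace(path)
  expect_equal(tr2$s_open, tr$s_open, tolerance = 1e-9)
  expect_equal(attr(tr2, "n_modes"), 2)
})

test_that("classification thresholds and dwell filtering behave as stated", {
  # steady open-state signature: all open, no transitions
  tr <- step_trace(40, 0.97, 0.82)
  cl <- classify_trajectory(tr)
  expect_true(all(cl$labels == "open"))
  expect_equal(n_transitions(cl), 0)
  expect_equal(cl$start_state, "open")

  # midpoint step with dwell 1: exactly one open->closed transition
  tr <- step_trace(40, 0.97, 0.82, 0.82, 0.97, at = 21)
  cl <- classify_trajectory(tr, dwell = 1)
  expect_equal(n_transitions(cl), 1)
  expect_equal(cl$transitions$from, "open")
  expect_equal(cl$transitions$to, "closed")
  expect_equal(cl$transitions$frame, 21)

  # jitter below thresholds never creates a transition
  set.seed(73)
  tr <- step_trace(200, 0.97, 0.82)
  tr$s_open <- tr$s_open + stats::runif(200, -0.01, 0.01)
  tr$s_closed <- tr$s_closed + stats::runif(200, -0.01, 0.01)
  expect_equal(n_transitions(classify_trajectory(tr)), 0)

  # a short excursion below dwell length is ignored
  tr <- step_trace(40, 0.97, 0.82)
  tr$s_open[15:17] <- 0.70; tr$s_closed[15:17] <- 0.99
  expect_equal(n_transitions(classify_trajectory(tr, dwell = 5)), 0)
  expect_equal(n_transitions(classify_trajectory(tr, dwell = 3)), 2)

  # intermediate frames do not terminate a dwell segment
  tr <- step_trace(40, 0.97, 0.82)
  tr$s_open[seq(2, 40, by = 2)] <- 0.90   # alternating intermediates
  cl <- classify_trajectory(tr, dwell = 5)
  expect_equal(n_transitions(cl), 0)
  expect_equal(cl$start_state, "open")

  expect_error(classify_trajectory(tr, high = 0.8, low = 0.9), "low < high")
})

test_that("transition tabulation reproduces the published rounding", {
  dwell_call <- classify_trajectory(step_trace(20, 0.97, 0.82), dwell = 1)
  switch_call <- classify_trajectory(
    step_trace(20, 0.97, 0.82, 0.82, 0.97, at = 11), dwell = 1)

  tab <- tabulate_transitions(rep(list(dwell_call), 90),
                              start_states = rep("Open", 90))
  expect_equal(tab$pct_no_transition, 100)
  expect_equal(tab$pct_transition, 0)

  # 83 quiet + 7 switching out of 90: 92% / 8% under half-up rounding
  calls <- c(rep(list(dwell_call), 83), rep(list(switch_call), 7))
  tab <- tabulate_transitions(calls, start_states = rep("Open", 90))
  expect_equal(tab$total, 90)
  expect_equal(tab$pct_no_transition, 92)
  expect_equal(tab$pct_transition, 8)

  tab <- tabulate_transitions(list(switch_call))
  expect_equal(tab$pct_transition, 100)

  # grouping by protein and start state
  tab <- tabulate_transitions(
    c(rep(list(dwell_call), 3), rep(list(switch_call), 1)),
    start_states = c("Open", "Open", "Closed", "Closed"),
    proteins = c("wt", "wt", "wt", "wt"))
  expect_equal(nrow(tab), 2)
  expect_error(tabulate_transitions(list()), "no state calls")
})
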