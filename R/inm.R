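# Instantaneous-normal-mode structural similarity, state classification and
# transition counting.
#
# Each trajectory snapshot is treated as its own elastic-network reference
# structure ("instantaneous" normal modes). The n lowest internal modes of
# the snapshot are matched against a pool of low-frequency template modes by
# maximum absolute overlap, and the similarity is the frequency-weighted
# mean of the matched absolute overlaps:
#
#   S = sum_i omega_m(i) |<v_i^query, v_m(i)^template>| / sum_i omega_m(i)
#
# with omega the matched template ("target") mode frequencies. S is in
# [0, 1]; S = 1 for identical mode sets. Eigenvector sign is arbitrary, so
# only absolute overlaps are ever used.

#' Match low-frequency modes of a query against a template pool
#'
#' For each of the `n` lowest-frequency query modes (in fixed ascending
#' frequency order) finds the template mode, among the `pool` lowest, with
#' the largest absolute inner product. Two query modes may match the same
#' template mode.
#'
#' @param query,template `inm_modes` objects of equal 3N dimensionality.
#' @param n number of query modes to match (default 2).
#' @param pool number of low-frequency template modes searched (default 10).
#' @return data.frame with columns `query`, `template`, `overlap`
#'   (absolute values).
#' @export
match_modes <- function(query, template, n = 2, pool = 10) {
  .assert(nrow(query$vectors) == nrow(template$vectors),
          "mode sets have different dimensionality (%d vs %d)",
          nrow(query$vectors), nrow(template$vectors))
  .assert(ncol(query$vectors) >= n,
          "query has %d retained modes, need %d", ncol(query$vectors), n)
  pool <- min(pool, ncol(template$vectors))
  .assert(pool >= n, "template pool (%d) smaller than n (%d)", pool, n)
  Q <- query$vectors[, seq_len(n), drop = FALSE]
  Tm <- template$vectors[, seq_len(pool), drop = FALSE]
  O <- abs(crossprod(Q, Tm))            # n x pool
  m <- apply(O, 1, which.max)
  data.frame(query = seq_len(n), template = m,
             overlap = O[cbind(seq_len(n), m)])
}

#' Frequency-weighted INM structural similarity
#'
#' The query modes are assumed computed after rigid superposition of the
#' query structure onto the template (see [similarity_trace()], which
#' enforces this); the metric itself is a pure mode-space quantity.
#'
#' @inheritParams match_modes
#' @return similarity in `[0, 1]`; exactly 1 when query and template modes
#'   coincide.
#' @export
inm_similarity <- function(query, template, n = 2, pool = 10) {
  mm <- match_modes(query, template, n = n, pool = pool)
  w <- template$frequencies[mm$template]
  .assert(all(w > 0), "matched template modes must have positive frequency")
  sum(w * mm$overlap) / sum(w)
}

# modes of the instantaneous elastic network at the given node coordinates
snapshot_modes <- function(coords, cutoff, n_modes) {
  net <- suppressWarnings(build_network(coords, cutoff = cutoff))
  normal_modes(net, n_modes = n_modes)
}

# modes of the same network after rigidly rotating the structure: each
# per-node 3-vector of every eigenvector transforms by the same rotation
# (row convention: fitted coords = coords %*% R); frequencies are unchanged
rotate_modes <- function(modes, R) {
  V <- modes$vectors
  out <- V
  for (k in seq_len(ncol(V))) {
    out[, k] <- as.numeric(t(matrix(V[, k], ncol = 3, byrow = TRUE) %*% R))
  }
  modes$vectors <- out
  modes
}

# resolve a template argument: either a list(structure=, mapping=) or a bare
# Structure (mapping defaults to identical residue numbers)
resolve_template <- function(tmpl, topo, node) {
  if (inherits(tmpl, "inm_structure")) tmpl <- list(structure = tmpl)
  s <- tmpl$structure
  mapping <- tmpl$mapping %||% map_residues(s, topo, 0)
  i_ref <- node_indices(s, mapping$resid_a, node)
  i_trj <- node_indices(topo, mapping$resid_b, node)
  list(coords = s$coords[i_ref, , drop = FALSE], idx = i_trj)
}

#' Similarity trace of a trajectory against open and closed templates
#'
#' For every retained snapshot: extract the mapped nodes, rigidly superpose
#' them onto each template, rebuild the elastic network at the superposed
#' snapshot geometry, compute its lowest `n` instantaneous normal modes and
#' score them against the template's modes.
#'
#' @param traj Trajectory.
#' @param open_template,closed_template either a Structure (residues assumed
#'   numbered like the trajectory topology) or a
#'   `list(structure =, mapping =)` with an [map_residues()] mapping whose
#'   `resid_a` refer to the template and `resid_b` to the topology.
#' @param n number of modes entering the similarity (default 2).
#' @param pool template mode pool searched during matching (default 10).
#' @param cutoff elastic-network cutoff in Angstrom (default 13).
#' @param node per-residue node atom (default `"CA"`).
#' @param stride_ps keep only snapshots at (approximately) this time
#'   spacing; `NULL` keeps every frame.
#' @return object of class `inm_trace`: data.frame with columns `time_ps`,
#'   `s_open`, `s_closed` and attributes `n_modes`, `cutoff`, `templates`.
#' @export
similarity_trace <- function(traj, open_template, closed_template,
                             n = 2, pool = 10, cutoff = 13, node = "CA",
                             stride_ps = NULL) {
  topo <- traj$topology
  op <- resolve_template(open_template, topo, node)
  cl <- resolve_template(closed_template, topo, node)
  .assert(nrow(op$coords) == nrow(cl$coords),
          "open and closed mappings resolve different node counts (%d vs %d)",
          nrow(op$coords), nrow(cl$coords))
  frames <- seq_len(n_frames(traj))
  if (!is.null(stride_ps)) {
    keep <- !duplicated(floor(traj$times / stride_ps))
    frames <- frames[keep]
  }
  open_modes <- snapshot_modes(op$coords, cutoff, pool)
  closed_modes <- snapshot_modes(cl$coords, cutoff, pool)
  shared_nodes <- identical(op$idx, cl$idx)
  score <- function(snap_nodes, tmpl_coords, tmpl_modes, snap_modes = NULL) {
    fit <- superpose(tmpl_coords, snap_nodes)
    q <- if (is.null(snap_modes)) {
      # modes of the superposed snapshot geometry
      tryCatch(snapshot_modes(fit$transform(snap_nodes), cutoff, n),
               error = function(e) e)
    } else {
      rotate_modes(snap_modes, fit$rotation)
    }
    if (inherits(q, "error")) return(q)
    inm_similarity(q, tmpl_modes, n = n, pool = pool)
  }
  s_open <- s_closed <- numeric(length(frames))
  for (k in seq_along(frames)) {
    xyz <- frame_coords(traj, frames[k])
    snap_modes <- NULL
    if (shared_nodes) {
      # one eigendecomposition per frame; per-template rotation afterwards
      snap_modes <- tryCatch(
        snapshot_modes(xyz[op$idx, , drop = FALSE], cutoff, n),
        error = function(e) e)
      if (inherits(snap_modes, "error")) {
        stop(sprintf("frame %d (t = %g ps): %s", frames[k],
                     traj$times[frames[k]],
                     conditionMessage(snap_modes)), call. = FALSE)
      }
    }
    so <- score(xyz[op$idx, , drop = FALSE], op$coords, open_modes,
                snap_modes)
    sc <- score(xyz[cl$idx, , drop = FALSE], cl$coords, closed_modes,
                snap_modes)
    for (v in list(so, sc)) {
      if (inherits(v, "error")) {
        stop(sprintf("frame %d (t = %g ps): %s", frames[k],
                     traj$times[frames[k]], conditionMessage(v)),
             call. = FALSE)
      }
    }
    s_open[k] <- so; s_closed[k] <- sc
  }
  out <- data.frame(time_ps = traj$times[frames], s_open = s_open,
                    s_closed = s_closed)
  attr(out, "n_modes") <- n
  attr(out, "cutoff") <- cutoff
  attr(out, "templates") <- c(open = "open", closed = "closed")
  class(out) <- c("inm_trace", "data.frame")
  out
}

#' Write / read a similarity trace as TSV
#'
#' Columns `time_ps`, `s_open`, `s_closed`; the resolved parameters are
#' echoed as `#`-prefixed header comments.
#'
#' @param trace an `inm_trace`.
#' @param path file path.
#' @return `path` (write) or an `inm_trace` (read).
#' @export
write_trace <- function(trace, path) {
  hdr <- c(sprintf("# n_modes = %s", attr(trace, "n_modes") %||% NA),
           sprintf("# cutoff = %s", attr(trace, "cutoff") %||% NA))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines("time_ps\ts_open\ts_closed", con)
  writeLines(sprintf("%.10g\t%.10g\t%.10g", trace$time_ps, trace$s_open,
                     trace$s_closed), con)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  lines <- readLines(path)
  hdr <- lines[grepl("^#", lines)]
  body <- lines[!grepl("^#", lines)]
  out <- utils::read.delim(text = paste(body, collapse = "\n"))
  grab <- function(key) {
    m <- sub(sprintf("^# %s = ", key), "", hdr[grepl(paste0("# ", key), hdr)])
    if (length(m)) suppressWarnings(as.numeric(m[1])) else NULL
  }
  attr(out, "n_modes") <- grab("n_modes")
  attr(out, "cutoff") <- grab("cutoff")
  class(out) <- c("inm_trace", "data.frame")
  out
}

#' Classify a similarity trace into open / closed / intermediate states
#'
#' A frame is `open` when `s_open >= high` and `s_closed <= low`, `closed`
#' in the mirror case, otherwise `intermediate`. A dwell segment is a run of
#' at least `dwell` consecutive same-state frames, where intermediate frames
#' never terminate a segment (only an opposing-state dwell does). A
#' transition is recorded at each change of state between successive dwell
#' segments.
#'
#' @param trace an `inm_trace` (or data.frame with `s_open`, `s_closed`).
#' @param high upper threshold (default 0.95: "same state" similarity).
#' @param low lower threshold (default 0.85: ceiling of the cross-state
#'   similarity band).
#' @param dwell minimum dwell length in frames (default 5).
#' @return object of class `inm_statecall`: list with `labels` (per frame),
#'   `segments` (data.frame state/start/end), `transitions` (data.frame
#'   frame/from/to), `start_state`, `thresholds`.
#' @export
classify_trajectory <- function(trace, high = 0.95, low = 0.85, dwell = 5) {
  .assert(low >= 0 && low < high && high <= 1, "need 0 <= low < high <= 1")
  .assert(dwell >= 1, "dwell must be >= 1")
  lab <- rep("intermediate", nrow(trace))
  lab[trace$s_open >= high & trace$s_closed <= low] <- "open"
  lab[trace$s_closed >= high & trace$s_open <= low] <- "closed"
  # runs over the subsequence of definite (non-intermediate) frames
  def_idx <- which(lab != "intermediate")
  segments <- data.frame(state = character(0), start = integer(0),
                         end = integer(0), nframes = integer(0))
  if (length(def_idx)) {
    r <- rle(lab[def_idx])
    stop_at <- cumsum(r$lengths)
    start_at <- c(1, utils::head(stop_at, -1) + 1)
    ok <- r$lengths >= dwell
    segments <- data.frame(
      state = r$values[ok],
      start = def_idx[start_at[ok]],
      end = def_idx[stop_at[ok]],
      nframes = r$lengths[ok])
  }
  transitions <- data.frame(frame = integer(0), from = character(0),
                            to = character(0))
  if (nrow(segments) >= 2) {
    chg <- which(segments$state[-1] != segments$state[-nrow(segments)])
    transitions <- data.frame(frame = segments$start[chg + 1],
                              from = segments$state[chg],
                              to = segments$state[chg + 1])
  }
  structure(list(labels = lab, segments = segments,
                 transitions = transitions,
                 start_state = if (nrow(segments)) segments$state[1] else
                   "intermediate",
                 thresholds = c(high = high, low = low, dwell = dwell)),
            class = "inm_statecall")
}

#' @export
print.inm_statecall <- function(x, ...) {
  cat(sprintf("<StateCall> %d frames, start %s, %d transition(s)\n",
              length(x$labels), x$start_state, nrow(x$transitions)))
  invisible(x)
}

#' Number of open<->closed transitions in a state call
#' @param call an `inm_statecall`.
#' @return integer transition count.
#' @export
n_transitions <- function(call) nrow(call$transitions)

#' Tabulate transition percentages over many trajectories
#'
#' Builds a table in the style of per-start-state transition statistics:
#' for each (protein, start state) group, the total trajectory count and the
#' percentage (nearest integer, halves up) with and without an
#' open/closed transition.
#'
#' @param calls list of `inm_statecall` objects.
#' @param start_states character vector tagging each call's start state;
#'   defaults to each call's own `start_state`.
#' @param proteins optional character tag per call (one row group per
#'   protein/start-state combination).
#' @return data.frame with columns `protein`, `start_state`, `total`,
#'   `pct_no_transition`, `pct_transition`.
#' @export
tabulate_transitions <- function(calls, start_states = NULL,
                                 proteins = NULL) {
  .assert(length(calls) >= 1, "no state calls supplied")
  if (is.null(start_states)) {
    start_states <- vapply(calls, `[[`, character(1), "start_state")
  }
  if (is.null(proteins)) proteins <- rep("protein", length(calls))
  has_tr <- vapply(calls, function(cl) n_transitions(cl) > 0, logical(1))
  key <- paste(proteins, start_states, sep = "\r")
  groups <- unique(key)
  out <- do.call(rbind, lapply(groups, function(g) {
    sel <- key == g
    total <- sum(sel)
    ntr <- sum(has_tr[sel])
    parts <- strsplit(g, "\r")[[1]]
    data.frame(protein = parts[1], start_state = parts[2], total = total,
               pct_no_transition = round_half_up(100 * (total - ntr) / total),
               pct_transition = round_half_up(100 * ntr / total))
  }))
  rownames(out) <- NULL
  out
}
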