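# Trajectory container: ordered coordinate frames over a shared topology.

#' Construct a Trajectory
#'
#' @param frames list of N x 3 coordinate matrices (Angstrom), or an
#'   N x 3 x F array.
#' @param times numeric frame time stamps in ps, strictly increasing.
#' @param topology the shared [new_structure()] Structure (atom identities).
#' @return object of class `inm_trajectory` with fields `coords`
#'   (N x 3 x F array), `times`, `topology`.
#' @export
new_trajectory <- function(frames, times, topology) {
  if (is.array(frames) && length(dim(frames)) == 3) {
    arr <- frames
  } else {
    .assert(length(frames) >= 1, "a Trajectory needs at least one frame")
    n <- nrow(frames[[1]])
    ok <- vapply(frames, function(f) identical(dim(as.matrix(f)),
                                               c(n, 3L)), logical(1))
    .assert(all(ok), "all frames must share atom count and ordering")
    arr <- array(unlist(frames), dim = c(n, 3, length(frames)))
  }
  .assert(dim(arr)[1] == n_atoms(topology),
          "frame atom count (%d) does not match topology (%d)",
          dim(arr)[1], n_atoms(topology))
  .assert(length(times) == dim(arr)[3], "times length must equal frame count")
  .assert(all(diff(times) > 0) || length(times) == 1,
          "times must be strictly increasing")
  structure(list(coords = arr, times = as.numeric(times), topology = topology),
            class = "inm_trajectory")
}

#' @export
print.inm_trajectory <- function(x, ...) {
  cat(sprintf("<Trajectory> %d frames x %d atoms, t = %g..%g ps\n",
              n_frames(x), dim(x$coords)[1], x$times[1],
              x$times[n_frames(x)]))
  invisible(x)
}

#' Number of frames in a Trajectory
#' @param traj Trajectory.
#' @return integer frame count.
#' @export
n_frames <- function(traj) dim(traj$coords)[3]

#' Extract one frame as an N x 3 matrix
#' @param traj Trajectory.
#' @param i frame index (1-based).
#' @return N x 3 coordinate matrix.
#' @export
frame_coords <- function(traj, i) {
  .assert(i >= 1 && i <= n_frames(traj), "frame %d out of range 1..%d",
          i, n_frames(traj))
  matrix(traj$coords[, , i], ncol = 3)
}

#' Read a Trajectory from a multi-model PDB file
#'
#' Every MODEL block becomes one frame; the first model supplies the
#' topology. Frame times default to `(0, dt, 2 dt, ...)`.
#'
#' @param pdb_source path or character vector of PDB lines.
#' @param dt frame spacing in ps (default 10, the usual snapshot stride).
#' @param chain_id optional chain filter applied to every model.
#' @return Trajectory.
#' @export
read_trajectory <- function(pdb_source, dt = 10, chain_id = NULL) {
  lines <- if (length(pdb_source) == 1 && !grepl("\n", pdb_source) &&
               file.exists(pdb_source)) readLines(pdb_source) else {
    unlist(strsplit(pdb_source, "\n", fixed = TRUE))
  }
  models <- split_models(lines)
  frames <- lapply(seq_along(models), function(k) {
    read_structure(lines, model_index = k, chain_id = chain_id)
  })
  topo <- frames[[1]]
  key0 <- with(topo$atoms, paste(chain, resid, icode, name))
  for (k in seq_along(frames)[-1]) {
    keyk <- with(frames[[k]]$atoms, paste(chain, resid, icode, name))
    .assert(identical(key0, keyk),
            "model %d atom ordering differs from model 1", k)
  }
  new_trajectory(lapply(frames, `[[`, "coords"),
                 times = (seq_along(models) - 1) * dt, topology = topo)
}

#' Write a Trajectory as multi-model PDB
#'
#' @param traj Trajectory.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  out <- character(0)
  for (k in seq_len(n_frames(traj))) {
    out <- c(out, sprintf("MODEL %8d", k),
             structure_to_pdb_lines(traj$topology, frame_coords(traj, k)),
             "ENDMDL")
  }
  writeLines(c(out, "END"), path)
  invisible(path)
}
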