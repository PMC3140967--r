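# Structure container and fixed-column PDB input/output.
#
# A Structure holds one conformation of one chain selection: an atom table
# (name, element, residue number + insertion code, residue name, chain) plus
# an N x 3 coordinate matrix in Angstrom and per-atom masses in amu.

#' Construct a Structure
#'
#' Low-level constructor for the package's structure container. Most users
#' will obtain structures from [read_structure()] or [make_hinge_protein()].
#'
#' @param atoms data.frame with columns `name`, `element`, `resid` (integer,
#'   author numbering), `icode` (insertion code, `""` if none), `resname`,
#'   `chain`.
#' @param coords numeric N x 3 matrix of positions in Angstrom.
#' @param masses optional numeric vector of per-atom masses in amu; derived
#'   from `element` when omitted.
#' @return object of class `inm_structure`.
#' @export
new_structure <- function(atoms, coords, masses = NULL) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3) stop("coords must be an N x 3 matrix", call. = FALSE)
  n <- nrow(coords)
  .assert(n >= 1, "a Structure needs at least one atom")
  .assert(nrow(atoms) == n, "atoms table (%d rows) does not match coords (%d)",
          nrow(atoms), n)
  .assert(all(is.finite(coords)), "coordinates must be finite")
  atoms$resid <- as.integer(atoms$resid)
  if (is.null(atoms$icode)) atoms$icode <- ""
  key <- paste(atoms$chain, atoms$resid, atoms$icode, atoms$name)
  .assert(!anyDuplicated(key),
          "duplicate atom records (chain/resid/icode/name must be unique)")
  if (is.null(masses)) masses <- element_mass(atoms$element)
  .assert(all(masses > 0), "all masses must be positive")
  structure(
    list(atoms = atoms, coords = unname(coords), masses = as.numeric(masses)),
    class = "inm_structure"
  )
}

#' @export
print.inm_structure <- function(x, ...) {
  cat(sprintf("<Structure> %d atoms, %d residues, chains: %s\n",
              nrow(x$coords), length(unique(paste(x$atoms$chain, x$atoms$resid))),
              paste(unique(x$atoms$chain), collapse = ",")))
  invisible(x)
}

#' Number of atoms in a Structure
#' @param s Structure.
#' @return integer atom count.
#' @export
n_atoms <- function(s) nrow(s$coords)

element_mass <- function(element) {
  el <- toupper(trimws(element))
  m <- .element_masses[el]
  if (anyNA(m)) {
    stop("no mass known for element(s): ",
         paste(unique(el[is.na(m)]), collapse = ", "), call. = FALSE)
  }
  unname(m)
}

# infer element symbol from a PDB atom name when columns 77-78 are blank;
# standard PDB right-justifies the element part within the 4-char name
guess_element <- function(atom_name) {
  nm <- trimws(atom_name)
  # strip remoteness indicators/digits: first alphabetic run
  first <- sub("^[0-9']*([A-Za-z]).*$", "\\1", nm)
  two <- toupper(substr(nm, 1, 2))
  ifelse(two %in% c("FE", "ZN", "MG", "SE", "MN") & nchar(nm) == 2,
         two, toupper(first))
}

parse_atom_lines <- function(lines, line_numbers) {
  get <- function(from, to) substr(lines, from, to)
  xyz <- suppressWarnings(cbind(
    as.numeric(get(31, 38)), as.numeric(get(39, 46)), as.numeric(get(47, 54))
  ))
  bad <- which(!stats::complete.cases(xyz))
  if (length(bad)) {
    stop(sprintf("malformed ATOM coordinate fields at line %d: '%s'",
                 line_numbers[bad[1]], lines[bad[1]]), call. = FALSE)
  }
  resid <- suppressWarnings(as.integer(get(23, 26)))
  if (anyNA(resid)) {
    bad <- which(is.na(resid))[1]
    stop(sprintf("malformed residue number at line %d: '%s'",
                 line_numbers[bad], lines[bad]), call. = FALSE)
  }
  element <- trimws(get(77, 78))
  name <- trimws(get(13, 16))
  element[element == ""] <- guess_element(name[element == ""])
  data.frame(
    name = name,
    altloc = get(17, 17),
    resname = trimws(get(18, 20)),
    chain = get(22, 22),
    resid = resid,
    icode = trimws(get(27, 27)),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    occupancy = suppressWarnings(as.numeric(get(55, 60))),
    element = element,
    stringsAsFactors = FALSE
  )
}

# split raw PDB lines into models; a file without MODEL records is one model
split_models <- function(lines) {
  starts <- grep("^MODEL", lines)
  if (!length(starts)) {
    return(list(seq_along(lines)))
  }
  ends <- grep("^ENDMDL", lines)
  .assert(length(ends) == length(starts), "unbalanced MODEL/ENDMDL records")
  lapply(seq_along(starts), function(k) seq(starts[k] + 1L, ends[k] - 1L))
}

#' Read a Structure from a PDB file or text
#'
#' Parses fixed-column ATOM records (HETATM is dropped) of one model and one
#' chain. Alternate locations keep the highest occupancy, ties resolved in
#' favour of altloc "A"; the choice is recorded in the `provenance` attribute.
#'
#' @param pdb_source path to a PDB file, or a character vector of PDB lines.
#' @param model_index 1-based model to read (default 1).
#' @param chain_id single chain identifier, or `NULL` to keep all chains.
#' @return a Structure ([new_structure()]).
#' @seealso [write_structure()], [read_trajectory()]
#' @export
read_structure <- function(pdb_source, model_index = 1L, chain_id = NULL) {
  lines <- if (length(pdb_source) == 1 && !grepl("\n", pdb_source) &&
               file.exists(pdb_source)) readLines(pdb_source) else {
    unlist(strsplit(pdb_source, "\n", fixed = TRUE))
  }
  models <- split_models(lines)
  .assert(model_index >= 1 && model_index <= length(models),
          "model %d not present; file has models 1..%d",
          model_index, length(models))
  idx <- models[[model_index]]
  keep <- idx[grepl("^ATOM  ", lines[idx])]
  .assert(length(keep) > 0, "no ATOM records in model %d", model_index)
  tab <- parse_atom_lines(lines[keep], keep)
  if (!is.null(chain_id)) {
    avail <- unique(tab$chain)
    .assert(chain_id %in% avail,
            "chain '%s' not found; available chains: %s",
            chain_id, paste(avail, collapse = ", "))
    tab <- tab[tab$chain == chain_id, , drop = FALSE]
  }
  tab <- resolve_altloc(tab)
  atoms <- tab[, c("name", "element", "resid", "icode", "resname", "chain")]
  rownames(atoms) <- NULL
  s <- new_structure(atoms, as.matrix(tab[, c("x", "y", "z")]))
  attr(s, "provenance") <- sprintf(
    "model %d%s; altloc policy: highest occupancy, ties -> 'A'",
    model_index, if (is.null(chain_id)) "" else paste0(", chain ", chain_id))
  s
}

resolve_altloc <- function(tab) {
  has_alt <- tab$altloc != " " & tab$altloc != ""
  if (!any(has_alt)) return(tab)
  key <- paste(tab$chain, tab$resid, tab$icode, tab$name)
  keep <- rep(TRUE, nrow(tab))
  for (k in unique(key[has_alt])) {
    rows <- which(key == k)
    if (length(rows) == 1) next
    occ <- tab$occupancy[rows]
    occ[is.na(occ)] <- 0
    best <- rows[occ == max(occ)]
    if (length(best) > 1) {
      a <- best[tab$altloc[best] == "A"]
      best <- if (length(a)) a[1] else best[1]
    } else best <- best[1]
    keep[setdiff(rows, best)] <- FALSE
  }
  tab[keep, , drop = FALSE]
}

format_atom_line <- function(serial, name, resname, chain, resid, icode,
                             xyz, element) {
  # PDB convention: atom names of <4 chars starting with a 1-letter element
  # are placed in columns 14-16
  nm <- if (nchar(name) < 4 && nchar(element) == 1) paste0(" ", name) else name
  sprintf("ATOM  %5d %-4s %-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial %% 100000L, nm, resname, chain, resid,
          ifelse(icode == "", " ", icode),
          xyz[1], xyz[2], xyz[3], 1.0, 0.0, element)
}

structure_to_pdb_lines <- function(s, coords = NULL) {
  xyz <- if (is.null(coords)) s$coords else coords
  a <- s$atoms
  vapply(seq_len(nrow(xyz)), function(i) {
    format_atom_line(i, a$name[i], a$resname[i], a$chain[i], a$resid[i],
                     a$icode[i], xyz[i, ], a$element[i])
  }, character(1))
}

#' Write a Structure as PDB
#'
#' @param s Structure.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(s, path) {
  writeLines(c(structure_to_pdb_lines(s), "END"), path)
  invisible(path)
}
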