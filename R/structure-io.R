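# Structures, trajectories, selections: reading, writing and validation.
#
# A Structure is an atom table: a tibble with columns
#   atom (name), element, resid (1-based), resname (3-letter), chain,
#   x, y, z (Angstrom)
# A Trajectory is a compact container: the shared atom table plus a
# frames x atoms x 3 coordinate array, per-frame times (ps) and a
# temperature label (K).

fs_structure_cols <- c("atom", "element", "resid", "resname", "chain",
                       "x", "y", "z")

new_structure <- function(df, model_id = 1L) {
  out <- tibble::as_tibble(df[fs_structure_cols])
  for (cc in c("x", "y", "z")) out[[cc]] <- unname(as.numeric(out[[cc]]))
  attr(out, "model_id") <- model_id
  class(out) <- c("fs_structure", class(tibble::tibble()))
  out
}

#' Validate and coerce an atom table to a structure
#'
#' @param df A data frame with columns `atom`, `resid`, `resname`, `chain`,
#'   `x`, `y`, `z` (an `element` column is inferred from atom names when
#'   absent).
#' @param model_id Integer model identifier kept as an attribute.
#' @return A structure tibble (class `fs_structure`).
#' @export
as_structure <- function(df, model_id = 1L) {
  need <- setdiff(fs_structure_cols, c("element", names(df)))
  if (length(need)) {
    abort(paste0("missing structure column(s): ", paste(need, collapse = ", ")))
  }
  if (!"element" %in% names(df)) df$element <- infer_element(df$atom)
  if (!all(is.finite(df$x) & is.finite(df$y) & is.finite(df$z))) {
    abort("non-finite coordinates in structure")
  }
  new_structure(df, model_id)
}

#' Coordinate matrix of a structure
#'
#' @param s A structure.
#' @return An N x 3 numeric matrix (Angstrom), rows in atom order.
#' @export
coords <- function(s) cbind(s$x, s$y, s$z)

set_coords <- function(s, xyz) {
  s$x <- xyz[, 1]; s$y <- xyz[, 2]; s$z <- xyz[, 3]
  s
}

heavy <- function(s) s[s$element != "H", , drop = FALSE]

#' Parse a (multi-model) PDB string
#'
#' Reads fixed-column `ATOM` records, honouring `MODEL`/`ENDMDL` framing;
#' a file without `MODEL` records is a single implicit model. Hydrogens
#' are kept. The first alternate location is retained; insertion codes
#' are rejected.
#'
#' @param text A PDB-format string (or character vector of lines).
#' @return A list of structures, one per model.
#' @seealso [read_pdb()], [write_pdb()]
#' @export
parse_pdb <- function(text) {
  lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]] else text
  rec <- substr(lines, 1, 6)
  is_atom <- rec == "ATOM  "
  is_model <- rec == "MODEL "
  is_end <- rec == "ENDMDL"
  if (!any(is_atom)) abort("no ATOM records found: empty input")

  model_of <- cumsum(is_model)
  if (!any(is_model)) model_of[] <- 1L
  atom_lines <- which(is_atom)

  parse_block <- function(idx) {
    ln <- lines[idx]
    short <- nchar(ln) < 54
    if (any(short)) {
      abort(sprintf("malformed ATOM line %d: fewer than 54 columns",
                    idx[short][1]))
    }
    name <- trimws(substr(ln, 13, 16))
    altloc <- substr(ln, 17, 17)
    resname <- trimws(substr(ln, 18, 20))
    chain <- substr(ln, 22, 22)
    resid_s <- trimws(substr(ln, 23, 26))
    icode <- substr(ln, 27, 27)
    if (any(icode != " ")) {
      abort(sprintf("insertion codes are not supported (line %d)",
                    idx[icode != " "][1]))
    }
    xyz <- suppressWarnings(cbind(
      as.numeric(substr(ln, 31, 38)),
      as.numeric(substr(ln, 39, 46)),
      as.numeric(substr(ln, 47, 54))))
    resid <- suppressWarnings(as.integer(resid_s))
    bad <- !is.finite(xyz[, 1]) | !is.finite(xyz[, 2]) | !is.finite(xyz[, 3]) |
      is.na(resid)
    if (any(bad)) {
      abort(sprintf("malformed ATOM line %d: unparsable coordinates or residue number",
                    idx[bad][1]))
    }
    el <- trimws(substr(ln, 77, 78))
    el <- ifelse(nchar(el) > 0,
                 paste0(toupper(substr(el, 1, 1)),
                        tolower(substr(el, 2, 2))),
                 "")
    el[!el %in% names(.element_mass)] <- NA_character_
    el[is.na(el)] <- infer_element(name[is.na(el)])
    keep <- altloc %in% c(" ", "A")
    tibble::tibble(atom = name, element = el, resid = resid,
                   resname = resname, chain = chain,
                   x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])[keep, ]
  }

  models <- sort(unique(model_of[atom_lines]))
  out <- lapply(seq_along(models), function(k) {
    idx <- atom_lines[model_of[atom_lines] == models[k]]
    new_structure(parse_block(idx), model_id = k)
  })
  out
}

#' Read structures from a PDB file
#'
#' @param path Path to a PDB file.
#' @return A list of structures, one per model.
#' @export
read_pdb <- function(path) parse_pdb(readLines(path, warn = FALSE))

#' Write structures as a PDB string
#'
#' Emits fixed-column `ATOM` records; `MODEL`/`ENDMDL` framing is used only
#' when more than one model is given (the single-model convention).
#'
#' @param models A structure or list of structures.
#' @param path Optional file path; when given the text is also written there.
#' @return The PDB text, invisibly when `path` is given.
#' @export
write_pdb <- function(models, path = NULL) {
  if (inherits(models, "fs_structure")) models <- list(models)
  fmt_model <- function(s) {
    xyz <- coords(s)
    if (any(abs(xyz) > 9999.999)) {
      abort("coordinate overflow: |coordinate| > 9999.999 cannot be written in %8.3f")
    }
    if (any(nchar(s$atom) > 4L)) abort("atom names longer than 4 characters")
    name_fmt <- ifelse(nchar(s$atom) < 4L & nchar(s$element) == 1L,
                       sprintf(" %-3s", s$atom), sprintf("%-4s", s$atom))
    sprintf("ATOM  %5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            seq_len(nrow(s)) %% 100000L, name_fmt, s$resname, s$chain,
            s$resid, xyz[, 1], xyz[, 2], xyz[, 3], 1, 0, s$element)
  }
  header <- "REMARK   generated by foldscape"
  if (length(models) == 0L) {
    txt <- paste0(paste(c(header, "END"), collapse = "\n"), "\n")
  } else if (length(models) == 1L) {
    txt <- paste0(paste(c(header, fmt_model(models[[1]]), "TER", "END"),
                        collapse = "\n"), "\n")
  } else {
    body <- unlist(lapply(seq_along(models), function(i) {
      c(sprintf("MODEL     %4d", i), fmt_model(models[[i]]), "TER", "ENDMDL")
    }))
    txt <- paste0(paste(c(header, body, "END"), collapse = "\n"), "\n")
  }
  if (!is.null(path)) {
    writeLines(txt, path, sep = "")
    return(invisible(txt))
  }
  txt
}

#' Extract the one-letter sequence of a chain
#'
#' One letter per distinct residue index, in order of residue number.
#'
#' @param s A structure.
#' @param chain_id Chain to extract; defaults to the only chain present.
#' @return A one-letter amino-acid string.
#' @export
extract_sequence <- function(s, chain_id = NULL) {
  if (is.null(chain_id)) {
    chains <- unique(s$chain)
    if (length(chains) > 1L) abort("multiple chains present: give chain_id")
    chain_id <- chains
  }
  sc <- s[s$chain == chain_id, ]
  if (nrow(sc) == 0L) abort(sprintf("chain '%s' not found", chain_id))
  ord <- order(sc$resid)
  keep <- !duplicated(sc$resid[ord])
  resnames <- sc$resname[ord][keep]
  bad <- !resnames %in% names(.aa1)
  if (any(bad)) {
    abort(sprintf("nonstandard residue(s): %s",
                  paste(unique(resnames[bad]), collapse = ", ")))
  }
  paste(.aa1[resnames], collapse = "")
}

#' Construct an atom selection
#'
#' @param ranges Inclusive 1-based residue ranges: a `c(start, end)` pair,
#'   a list of such pairs, or a two-column matrix.
#' @param atom_class One of `"mainchain"` (N, CA, C, O), `"heavy"`
#'   (all non-hydrogen), `"all"`, or `"CA"`.
#' @param chain_id Optional chain restriction.
#' @return A selection object.
#' @export
selection <- function(ranges, atom_class = c("mainchain", "heavy", "all", "CA"),
                      chain_id = NULL) {
  atom_class <- match.arg(atom_class)
  if (is.numeric(ranges) && is.null(dim(ranges))) ranges <- list(ranges)
  if (is.list(ranges)) ranges <- do.call(rbind, ranges)
  ranges <- matrix(as.integer(ranges), ncol = 2)
  if (nrow(ranges) == 0L || any(ranges[, 1] > ranges[, 2])) {
    abort("selection ranges must be non-empty with start <= end")
  }
  structure(list(ranges = ranges, atom_class = atom_class,
                 chain_id = chain_id),
            class = "fs_selection")
}

# built-in DS119 selections
#' @rdname selection
#' @export
sel_helix <- function(atom_class = "mainchain")
  selection(ds119_segments()$helix, atom_class)

#' @rdname selection
#' @export
sel_sheet <- function(atom_class = "mainchain")
  selection(ds119_segments()$sheet, atom_class)

#' @rdname selection
#' @export
sel_fold <- function(atom_class = "mainchain")
  selection(rbind(ds119_segments()$sheet[1, ], ds119_segments()$helix,
                  ds119_segments()$sheet[2, ]), atom_class)

#' Resolve a selection to atom indices
#'
#' @param s A structure.
#' @param sel A [selection()].
#' @return Integer atom row indices in structure order; an empty match is
#'   an error so downstream code never silently computes on nothing.
#' @export
resolve_selection <- function(s, sel) {
  in_range <- rep(FALSE, nrow(s))
  for (k in seq_len(nrow(sel$ranges))) {
    in_range <- in_range |
      (s$resid >= sel$ranges[k, 1] & s$resid <= sel$ranges[k, 2])
  }
  keep <- in_range
  if (!is.null(sel$chain_id)) keep <- keep & s$chain == sel$chain_id
  keep <- keep & switch(sel$atom_class,
    mainchain = s$atom %in% c("N", "CA", "C", "O"),
    heavy = s$element != "H",
    CA = s$atom == "CA",
    all = TRUE)
  idx <- which(keep)
  if (length(idx) == 0L) abort("selection resolves to zero atoms")
  idx
}

#' Assemble frames into a trajectory
#'
#' @param frames A list of structures sharing identical atom ordering.
#' @param times_ps Strictly increasing frame times in picoseconds.
#' @param temperature Temperature label in Kelvin.
#' @return A trajectory object (`fs_traj`).
#' @export
as_trajectory <- function(frames, times_ps, temperature = NA_real_) {
  if (length(frames) == 0L) abort("empty trajectory")
  if (length(times_ps) != length(frames)) {
    abort("length(times_ps) must equal number of frames")
  }
  if (any(diff(times_ps) <= 0)) abort("frame times must be strictly increasing")
  meta <- frames[[1]][c("atom", "element", "resid", "resname", "chain")]
  for (f in frames[-1]) {
    if (!identical(f$atom, meta$atom) || !identical(f$resid, meta$resid) ||
        !identical(f$chain, meta$chain)) {
      abort("all frames must share identical atom ordering")
    }
  }
  xyz <- array(NA_real_, dim = c(length(frames), nrow(meta), 3L))
  for (i in seq_along(frames)) xyz[i, , ] <- coords(frames[[i]])
  structure(list(atoms = meta, xyz = xyz, times_ps = as.numeric(times_ps),
                 temperature = temperature),
            class = "fs_traj")
}

#' @export
print.fs_traj <- function(x, ...) {
  cat(sprintf("<fs_traj> %d frames x %d atoms, t = %.6g..%.6g ps, T = %s K\n",
              n_frames(x), nrow(x$atoms), min(x$times_ps), max(x$times_ps),
              format(x$temperature)))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj A trajectory.
#' @return Integer frame count.
#' @export
n_frames <- function(traj) dim(traj$xyz)[1]

#' Extract one frame of a trajectory as a structure
#' @param traj A trajectory.
#' @param i Frame index.
#' @return A structure.
#' @export
traj_frame <- function(traj, i) {
  s <- traj$atoms
  s$x <- traj$xyz[i, , 1]; s$y <- traj$xyz[i, , 2]; s$z <- traj$xyz[i, , 3]
  new_structure(s, model_id = i)
}

#' Subset the frames of a trajectory
#' @param traj A trajectory.
#' @param idx Frame indices to keep (in increasing order).
#' @return A trajectory.
#' @export
traj_subset <- function(traj, idx) {
  structure(list(atoms = traj$atoms,
                 xyz = traj$xyz[idx, , , drop = FALSE],
                 times_ps = traj$times_ps[idx],
                 temperature = traj$temperature),
            class = "fs_traj")
}

#' Read a trajectory from a multi-model PDB file
#'
#' @param path PDB file path.
#' @param times_ps Frame times; defaults to 0, 1, 2, ... ps.
#' @param temperature Temperature label (K).
#' @return A trajectory.
#' @export
read_traj_pdb <- function(path, times_ps = NULL, temperature = NA_real_) {
  models <- read_pdb(path)
  if (is.null(times_ps)) times_ps <- seq_along(models) - 1
  as_trajectory(models, times_ps, temperature)
}

#' Write / read trajectories in extended XYZ format
#'
#' The comment line of every frame carries `t=<ps> T=<K>`; each atom row
#' carries element, coordinates and the atom/residue metadata needed to
#' rebuild the structure, so `read_xyz(write_xyz(traj))` round-trips.
#'
#' @param traj A trajectory.
#' @param path Output (or input) file path.
#' @return `write_xyz` returns `path` invisibly; `read_xyz` a trajectory.
#' @export
write_xyz <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  a <- traj$atoms
  for (i in seq_len(n_frames(traj))) {
    writeLines(as.character(nrow(a)), con)
    writeLines(sprintf("t=%.6g T=%.6g", traj$times_ps[i], traj$temperature), con)
    writeLines(sprintf("%-2s %12.5f %12.5f %12.5f %-4s %4d %-3s %1s",
                       a$element, traj$xyz[i, , 1], traj$xyz[i, , 2],
                       traj$xyz[i, , 3], a$atom, a$resid, a$resname, a$chain),
               con)
  }
  invisible(path)
}

#' @rdname write_xyz
#' @export
read_xyz <- function(path) {
  lines <- readLines(path, warn = FALSE)
  frames <- list(); times <- numeric(); temp <- NA_real_
  i <- 1L
  while (i <= length(lines)) {
    n <- as.integer(lines[i])
    if (is.na(n)) abort(sprintf("bad atom count at line %d", i))
    hdr <- lines[i + 1L]
    t_ps <- as.numeric(sub(".*t=([-0-9.eE+]+).*", "\\1", hdr))
    temp <- as.numeric(sub(".*T=([-0-9.eE+NA]+).*", "\\1", hdr))
    rows <- lines[(i + 2L):(i + 1L + n)]
    parts <- strsplit(trimws(rows), "[[:space:]]+")
    m <- do.call(rbind, parts)
    frames[[length(frames) + 1L]] <- new_structure(tibble::tibble(
      atom = m[, 5], element = m[, 1],
      resid = as.integer(m[, 6]), resname = m[, 7], chain = m[, 8],
      x = as.numeric(m[, 2]), y = as.numeric(m[, 3]), z = as.numeric(m[, 4])))
    times <- c(times, t_ps)
    i <- i + 2L + n
  }
  as_trajectory(frames, times, temp)
}
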