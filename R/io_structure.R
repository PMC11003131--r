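# Structure and trajectory readers/writers.
#
# Internal coordinates are always nm. PDB and XYZ store Angstrom (converted
# on read/write); GRO stores nm. Only orthorhombic boxes are supported;
# triclinic input raises an explicit unsupported-feature error.

#' Built-in element masses (amu)
#'
#' @return named numeric vector of atomic masses.
#' @export
element_masses <- function() {
  c(H = 1.008, D = 2.014, B = 10.811, C = 12.011, N = 14.007, O = 15.999,
    F = 18.998, Na = 22.990, Mg = 24.305, P = 30.974, S = 32.06,
    Cl = 35.45, K = 39.098, Ca = 40.078, Mn = 54.938, Fe = 55.845,
    Co = 58.933, Ni = 58.693, Cu = 63.546, Zn = 65.38, Se = 78.971,
    Br = 79.904, I = 126.904)
}

# guess an element symbol from an atom name: strip digits, try two-letter
# then one-letter symbol.
guess_element <- function(name) {
  base <- gsub("[0-9'\"]+", "", trimws(name))
  known <- names(element_masses())
  two <- paste0(toupper(substr(base, 1, 1)), tolower(substr(base, 2, 2)))
  if (nchar(base) >= 2 && two %in% known) return(two)
  one <- toupper(substr(base, 1, 1))
  if (one %in% known) return(one)
  base
}

mass_for <- function(element, name, overrides = NULL) {
  if (!is.null(overrides) && name %in% names(overrides))
    return(as.numeric(overrides[[name]]))
  m <- element_masses()[element]
  if (is.na(m))
    stop(sprintf("unknown element '%s' for atom '%s'; supply a mass override",
                 element, name), call. = FALSE)
  unname(m)
}

parse_error <- function(path, line, msg) {
  stop(sprintf("%s: line %d: %s", basename(path), line, msg), call. = FALSE)
}

num_field <- function(s, path, line, what) {
  v <- suppressWarnings(as.numeric(s))
  if (any(is.na(v))) parse_error(path, line, sprintf("malformed %s '%s'", what, s))
  v
}

#' Read a molecular structure file
#'
#' Supported formats: PDB (`ATOM`/`HETATM` records, Angstrom; the first
#' `MODEL` only), GRO (nm) and XYZ (Angstrom; the first frame only).
#' Coordinates are converted to nm. Masses come from the built-in element
#' table ([element_masses()]); unknown elements are an error unless a mass
#' override is supplied.
#'
#' @param path file path.
#' @param format one of `"pdb"`, `"gro"`, `"xyz"`; default guessed from the
#'   file extension.
#' @param mass_overrides optional named list/vector mapping atom names to
#'   masses (amu).
#' @return `list(topology =, frame =)`: a [molecular_topology()] skeleton
#'   (no bonds, no core annotation) and a [new_frame()].
#' @export
read_structure <- function(path, format = NULL, mass_overrides = NULL) {
  .assert(file.exists(path), "file not found: %s", path)
  if (is.null(format)) format <- tolower(tools::file_ext(path))
  format <- match.arg(format, c("pdb", "gro", "xyz"))
  switch(format,
         pdb = read_pdb_structure(path, mass_overrides),
         gro = read_gro_block(path, mass_overrides),
         xyz = read_xyz_structure(path, mass_overrides))
}

read_pdb_structure <- function(path, mass_overrides = NULL) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0) parse_error(path, 1, "empty file")
  name <- character(0); element <- character(0); mol <- integer(0)
  resname <- character(0)
  xyz <- NULL; box <- NULL
  n_models <- 0
  for (ln in seq_along(lines)) {
    l <- lines[ln]
    rec <- substr(l, 1, 6)
    if (startsWith(rec, "MODEL")) {
      n_models <- n_models + 1
      if (n_models > 1) break
    } else if (startsWith(rec, "ENDMDL")) {
      break
    } else if (startsWith(rec, "CRYST1")) {
      if (nchar(l) < 54) parse_error(path, ln, "truncated CRYST1 record")
      abc <- num_field(c(substr(l, 7, 15), substr(l, 16, 24), substr(l, 25, 33)),
                       path, ln, "cell length")
      ang <- num_field(c(substr(l, 34, 40), substr(l, 41, 47), substr(l, 48, 54)),
                       path, ln, "cell angle")
      if (any(abs(ang - 90) > 1e-6))
        stop(sprintf("%s: line %d: triclinic boxes are not supported",
                     basename(path), ln), call. = FALSE)
      if (all(abc > 1e-6)) box <- abc / 10  # A -> nm
    } else if (rec == "ATOM  " || rec == "HETATM") {
      if (nchar(l) < 54) parse_error(path, ln, "truncated ATOM/HETATM record")
      nm <- trimws(substr(l, 13, 16))
      if (!nzchar(nm)) parse_error(path, ln, "empty atom name")
      co <- num_field(c(substr(l, 31, 38), substr(l, 39, 46), substr(l, 47, 54)),
                      path, ln, "coordinate")
      el <- trimws(substr(l, 77, 78))
      if (!nzchar(el)) el <- guess_element(nm)
      el <- paste0(toupper(substr(el, 1, 1)), tolower(substr(el, 2, 2)))
      resseq <- suppressWarnings(as.integer(trimws(substr(l, 23, 26))))
      if (is.na(resseq)) resseq <- 1L
      name <- c(name, nm); element <- c(element, el); mol <- c(mol, resseq)
      resname <- c(resname, trimws(substr(l, 18, 20)))
      xyz <- rbind(xyz, co)
    }
  }
  if (is.null(xyz)) parse_error(path, length(lines), "no ATOM/HETATM records found")
  mass <- vapply(seq_along(name),
                 function(i) mass_for(element[i], name[i], mass_overrides),
                 numeric(1))
  atoms <- data.frame(name = name, element = element, mass = mass,
                      molecule_id = mol, stringsAsFactors = FALSE)
  atoms$resname <- resname
  topo <- molecular_topology(
    molecule_name = tools::file_path_sans_ext(basename(path)),
    atoms = atoms)
  list(topology = topo, frame = new_frame(xyz / 10, box = box, time = 0))
}

#' Write a single frame as PDB
#'
#' Coordinates are written in Angstrom with three decimals; molecule ids go
#' to the residue-sequence field.
#'
#' @param frame a `cg_frame` (nm).
#' @param topology the matching [molecular_topology()].
#' @param path output path.
#' @param resnames optional character vector of residue names per atom
#'   (default `"MOL"`).
#' @return `path`, invisibly.
#' @export
write_pdb <- function(frame, topology, path, resnames = NULL) {
  at <- topology$atoms
  X <- frame$coordinates * 10
  if (is.null(resnames)) resnames <- rep("MOL", nrow(at))
  con <- file(path, "w"); on.exit(close(con))
  if (!is.null(frame$box))
    writeLines(sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                       frame$box[1] * 10, frame$box[2] * 10, frame$box[3] * 10,
                       90, 90, 90), con)
  for (i in seq_len(nrow(at))) {
    writeLines(sprintf(
      "ATOM  %5d %-4s %-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      i %% 100000, substr(at$name[i], 1, 4), substr(resnames[i], 1, 3), "A",
      at$molecule_id[i] %% 10000, X[i, 1], X[i, 2], X[i, 3], 1, 0,
      substr(at$element[i], 1, 2)), con)
  }
  writeLines("END", con)
  invisible(path)
}

read_xyz_frames <- function(path, max_frames = Inf, mass_overrides = NULL) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0 || all(!nzchar(trimws(lines))))
    parse_error(path, 1, "empty file")
  frames <- list(); names_out <- NULL
  ln <- 1; fi <- 0
  while (ln <= length(lines) && fi < max_frames) {
    if (!nzchar(trimws(lines[ln]))) { ln <- ln + 1; next }
    n <- suppressWarnings(as.integer(trimws(lines[ln])))
    if (is.na(n) || n < 1)
      parse_error(path, ln, sprintf("expected atom count, got '%s'", lines[ln]))
    fi <- fi + 1
    if (ln + 1 + n > length(lines))
      parse_error(path, length(lines),
                  sprintf("frame %d: truncated (expected %d atom lines)", fi, n))
    comment <- lines[ln + 1]
    nm <- character(n); X <- matrix(0, n, 3)
    for (i in seq_len(n)) {
      lni <- ln + 1 + i
      tok <- strsplit(trimws(lines[lni]), "[[:space:]]+")[[1]]
      if (length(tok) < 4)
        stop(sprintf("%s: frame %d, line %d: malformed atom line", basename(path),
                     fi, lni), call. = FALSE)
      nm[i] <- tok[1]
      v <- suppressWarnings(as.numeric(tok[2:4]))
      if (any(is.na(v)))
        stop(sprintf("%s: frame %d, line %d: malformed coordinate", basename(path),
                     fi, lni), call. = FALSE)
      X[i, ] <- v
    }
    tm <- fi - 1
    m <- regmatches(comment, regexec("t=\\s*([-0-9.eE+]+)", comment))[[1]]
    if (length(m) == 2) tm <- as.numeric(m[2])
    box <- NULL
    mb <- regmatches(comment,
                     regexec("box=\\s*([-0-9.eE+]+)[ ,]+([-0-9.eE+]+)[ ,]+([-0-9.eE+]+)",
                             comment))[[1]]
    if (length(mb) == 4) box <- as.numeric(mb[2:4]) / 10  # A -> nm
    frames[[fi]] <- new_frame(X / 10, box = box, time = tm)  # A -> nm
    if (is.null(names_out)) names_out <- nm
    if (length(nm) != length(names_out))
      stop(sprintf("%s: frame %d has %d atoms, expected %d", basename(path),
                   fi, length(nm), length(names_out)), call. = FALSE)
    ln <- ln + 2 + n
  }
  list(frames = frames, names = names_out)
}

read_xyz_structure <- function(path, mass_overrides = NULL) {
  parsed <- read_xyz_frames(path, max_frames = 1)
  nm <- parsed$names
  el <- vapply(nm, guess_element, character(1))
  mass <- vapply(seq_along(nm), function(i) mass_for(el[i], nm[i], mass_overrides),
                 numeric(1))
  topo <- molecular_topology(
    molecule_name = tools::file_path_sans_ext(basename(path)),
    atoms = data.frame(name = nm, element = el, mass = mass,
                       molecule_id = 1L, stringsAsFactors = FALSE))
  list(topology = topo, frame = parsed$frames[[1]])
}

read_gro_frames <- function(path, max_frames = Inf, mass_overrides = NULL) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0) parse_error(path, 1, "empty file")
  frames <- list(); names_out <- NULL; mols_out <- NULL
  ln <- 1; fi <- 0
  while (ln <= length(lines) && fi < max_frames) {
    if (!nzchar(trimws(lines[ln])) && ln == length(lines)) break
    fi <- fi + 1
    if (ln + 1 > length(lines)) parse_error(path, ln, "truncated GRO header")
    n <- suppressWarnings(as.integer(trimws(lines[ln + 1])))
    if (is.na(n) || n < 1)
      parse_error(path, ln + 1, sprintf("expected atom count, got '%s'",
                                        lines[ln + 1]))
    if (ln + 2 + n > length(lines))
      parse_error(path, length(lines),
                  sprintf("frame %d: truncated (expected %d atom lines + box)", fi, n))
    nm <- character(n); mol <- integer(n); X <- matrix(0, n, 3)
    for (i in seq_len(n)) {
      l <- lines[ln + 1 + i]
      if (nchar(l) < 44)
        stop(sprintf("%s: frame %d, line %d: GRO atom line too short",
                     basename(path), fi, ln + 1 + i), call. = FALSE)
      mol[i] <- suppressWarnings(as.integer(trimws(substr(l, 1, 5))))
      nm[i] <- trimws(substr(l, 11, 15))
      v <- suppressWarnings(as.numeric(c(substr(l, 21, 28), substr(l, 29, 36),
                                         substr(l, 37, 44))))
      if (any(is.na(v)) || is.na(mol[i]) || !nzchar(nm[i]))
        stop(sprintf("%s: frame %d, line %d: malformed GRO atom line",
                     basename(path), fi, ln + 1 + i), call. = FALSE)
      X[i, ] <- v
    }
    boxtok <- strsplit(trimws(lines[ln + 2 + n]), "[[:space:]]+")[[1]]
    bv <- suppressWarnings(as.numeric(boxtok))
    if (any(is.na(bv)) || length(bv) < 3)
      parse_error(path, ln + 2 + n, "malformed box line")
    if (length(bv) > 3 && any(abs(bv[4:length(bv)]) > 1e-9))
      stop(sprintf("%s: line %d: triclinic boxes are not supported",
                   basename(path), ln + 2 + n), call. = FALSE)
    box <- if (all(bv[1:3] > 1e-9)) bv[1:3] else NULL
    tm <- fi - 1
    m <- regmatches(lines[ln], regexec("t=\\s*([-0-9.eE+]+)", lines[ln]))[[1]]
    if (length(m) == 2) tm <- as.numeric(m[2])
    frames[[fi]] <- new_frame(X, box = box, time = tm)
    if (is.null(names_out)) { names_out <- nm; mols_out <- mol }
    if (length(nm) != length(names_out))
      stop(sprintf("%s: frame %d has %d atoms, expected %d", basename(path),
                   fi, length(nm), length(names_out)), call. = FALSE)
    ln <- ln + 3 + n
    while (ln <= length(lines) && !nzchar(trimws(lines[ln]))) ln <- ln + 1
  }
  list(frames = frames, names = names_out, mols = mols_out)
}

read_gro_block <- function(path, mass_overrides = NULL) {
  parsed <- read_gro_frames(path, max_frames = 1)
  nm <- parsed$names
  el <- vapply(nm, guess_element, character(1))
  mass <- vapply(seq_along(nm), function(i) mass_for(el[i], nm[i], mass_overrides),
                 numeric(1))
  topo <- molecular_topology(
    molecule_name = tools::file_path_sans_ext(basename(path)),
    atoms = data.frame(name = nm, element = el, mass = mass,
                       molecule_id = parsed$mols, stringsAsFactors = FALSE))
  list(topology = topo, frame = parsed$frames[[1]])
}

#' Read a multi-frame trajectory
#'
#' Supported formats: multi-frame XYZ (Angstrom, converted to nm) and
#' concatenated multi-frame GRO (nm). The atom count must be constant across
#' frames; a deviating frame is an error naming the frame index. Frame times
#' are parsed from `t=` tags in the comment/title lines when present,
#' otherwise numbered 0, 1, 2, ... ps.
#'
#' @param path file path.
#' @param format `"xyz"` or `"gro"`; default guessed from the extension.
#' @return a [new_trajectory()] with attribute `"atom_names"`.
#' @export
read_trajectory <- function(path, format = NULL) {
  .assert(file.exists(path), "file not found: %s", path)
  if (is.null(format)) format <- tolower(tools::file_ext(path))
  format <- match.arg(format, c("xyz", "gro"))
  parsed <- if (format == "xyz") read_xyz_frames(path) else read_gro_frames(path)
  traj <- trajectory_from_frames(parsed$frames)
  attr(traj, "atom_names") <- parsed$names
  traj
}

#' Write a trajectory
#'
#' XYZ is written in Angstrom with six decimals (round-trips to 1e-6 A);
#' GRO in nm with three decimals (1e-3 nm). Frame times and boxes are
#' embedded in the comment/title lines as `t=` and `box=` tags (box in
#' Angstrom for XYZ, nm for GRO via the box line).
#'
#' @param traj a `cg_trajectory`.
#' @param path output path.
#' @param format `"xyz"` or `"gro"`; default guessed from the extension.
#' @param atom_names optional atom names (default from the trajectory's
#'   `"atom_names"` attribute, else `"X1"`, `"X2"`, ...).
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path, format = NULL, atom_names = NULL) {
  .assert(inherits(traj, "cg_trajectory"), "traj must be a cg_trajectory")
  if (is.null(format)) format <- tolower(tools::file_ext(path))
  format <- match.arg(format, c("xyz", "gro"))
  if (is.null(atom_names)) atom_names <- attr(traj, "atom_names")
  if (is.null(atom_names)) atom_names <- paste0("X", seq_len(traj$atom_count))
  con <- file(path, "w"); on.exit(close(con))
  n <- traj$atom_count
  for (f in seq_len(traj$n_frames)) {
    X <- traj$coords[, , f, drop = FALSE][, , 1, drop = FALSE]
    dim(X) <- c(n, 3)
    box <- if (is.null(traj$box)) NULL else traj$box[f, ]
    if (format == "xyz") {
      XA <- X * 10
      hdr <- sprintf("frame %d t= %.6f", f, traj$times[f])
      if (!is.null(box))
        hdr <- paste0(hdr, sprintf(" box= %.6f %.6f %.6f", box[1] * 10,
                                   box[2] * 10, box[3] * 10))
      writeLines(as.character(n), con)
      writeLines(hdr, con)
      writeLines(sprintf("%-5s %14.6f %14.6f %14.6f", atom_names,
                         XA[, 1], XA[, 2], XA[, 3]), con)
    } else {
      writeLines(sprintf("cgstack t= %.6f", traj$times[f]), con)
      writeLines(sprintf("%5d", n), con)
      writeLines(sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                         rep(1L, n), "MOL", substr(atom_names, 1, 5),
                         seq_len(n) %% 100000, X[, 1], X[, 2], X[, 3]), con)
      if (is.null(box)) writeLines("   0.00000   0.00000   0.00000", con)
      else writeLines(sprintf("%10.5f%10.5f%10.5f", box[1], box[2], box[3]), con)
    }
  }
  invisible(path)
}
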