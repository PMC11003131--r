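# Scene PDB round-trip. Each molecule becomes one residue; the species label
# is encoded in the residue name: "STK" for stackers, the additive's own
# name (truncated to 4 characters, upper case) for "additive:<name>".
# On re-reading, 4-site "STK" residues get the square-planar stacker
# annotation (core = all sites, reference_axis = (3, 1), matching the
# synthetic stacker template); every other residue is an additive whose
# species is "additive:<resname>".

species_to_resname <- function(species) {
  if (species == "stacker") return("STK")
  nm <- sub("^additive:", "", species)
  toupper(substr(ifelse(nzchar(nm), nm, "ADD"), 1, 3))
}

#' Write a scene as PDB
#'
#' @param scene a `cg_scene`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_scene <- function(scene, path) {
  .assert(inherits(scene, "cg_scene"), "scene must be a cg_scene")
  con <- file(path, "w"); on.exit(close(con))
  if (!is.null(scene$box))
    writeLines(sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                       scene$box[1] * 10, scene$box[2] * 10, scene$box[3] * 10,
                       90, 90, 90), con)
  serial <- 0L
  for (m in seq_along(scene$molecules)) {
    mol <- scene$molecules[[m]]
    res <- species_to_resname(mol$species)
    X <- mol$coords * 10
    at <- mol$topology$atoms
    for (i in seq_len(nrow(X))) {
      serial <- serial + 1L
      writeLines(sprintf(
        "ATOM  %5d %-4s %-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        serial %% 100000, substr(at$name[i], 1, 4), res, "A", m %% 10000,
        X[i, 1], X[i, 2], X[i, 3], 1, 0, substr(at$element[i], 1, 2)), con)
    }
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a scene from PDB
#'
#' Inverse of [write_scene()]: residues become molecules, residue name
#' `"STK"` maps to species `"stacker"` (with the 4-site planar-core
#' annotation when the residue has exactly 4 atoms), anything else to
#' `"additive:<resname>"`.
#'
#' @param path PDB path.
#' @return a `cg_scene`.
#' @export
read_scene <- function(path) {
  parsed <- read_pdb_structure(path)
  at <- parsed$topology$atoms
  X <- parsed$frame$coordinates
  # residues delimited by changes in molecule_id (resSeq wraps at 10000)
  brk <- c(TRUE, diff(at$molecule_id) != 0)
  grp <- cumsum(brk)
  mols <- lapply(split(seq_len(nrow(at)), grp), function(idx) {
    sub <- at[idx, , drop = FALSE]
    coords <- X[idx, , drop = FALSE]
    resname <- sub$resname[1]
    if (identical(resname, "STK") && length(idx) == 4) {
      topo <- molecular_topology("stacker",
        data.frame(name = sub$name, element = sub$element, mass = sub$mass,
                   molecule_id = 1L, stringsAsFactors = FALSE),
        bonds = rbind(c(1L, 2L), c(2L, 3L), c(3L, 4L), c(4L, 1L)),
        core_atoms = 1:4, reference_axis = c(3L, 1L))
      species <- "stacker"
    } else {
      topo <- molecular_topology(tolower(resname),
        data.frame(name = sub$name, element = sub$element, mass = sub$mass,
                   molecule_id = 1L, stringsAsFactors = FALSE))
      species <- if (identical(resname, "STK")) "stacker"
                 else paste0("additive:", resname)
    }
    list(topology = topo, coords = coords, species = species)
  })
  new_scene(unname(mols), box = parsed$frame$box)
}
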