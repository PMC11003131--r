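# Force-field parameter export: ITP-like bonded sections (GROMACS dialect,
# funct 1 harmonic bonds, funct 2 harmonic angles, 1-based bead indices) and
# a lossless structured JSON serialization.

#' Export force-field parameters
#'
#' The `itp` dialect writes a `[ bonds ]` section with lines
#' `i j funct b0 kb` (funct 1, b0 in nm, kb in kJ mol^-1 nm^-2) and an
#' `[ angles ]` section with `i j k funct th0 cth` (funct 2, th0 in degrees,
#' cth in kJ mol^-1 rad^-2), bead indices 1-based. The `structured` dialect
#' is a JSON document that round-trips losslessly through
#' [import_parameters()], including Lennard-Jones pair parameters and the
#' cutoff, which the ITP dialect omits.
#'
#' @param ff a [force_field()] covering every term of `topology`.
#' @param topology the [cg_topology()] whose terms are exported.
#' @param format `"itp"` or `"structured"`.
#' @param path optional output path; when `NULL` the text is only returned.
#' @return the exported text, invisibly when `path` is given.
#' @export
export_parameters <- function(ff, topology, format = c("itp", "structured"),
                              path = NULL) {
  format <- match.arg(format)
  pars <- collect_params(ff, topology)  # errors on missing terms
  txt <- if (format == "itp") export_itp(ff, topology, pars)
         else export_structured(ff, topology, pars)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

export_itp <- function(ff, topology, pars) {
  out <- c("; coarse-grained bonded parameters (cgstack)",
           "; b0 nm, kb kJ mol^-1 nm^-2, th0 deg, cth kJ mol^-1 rad^-2")
  bt <- topology$bond_terms
  if (nrow(bt) > 0) {
    out <- c(out, "", "[ bonds ]", ";  i    j funct         b0         kb")
    for (r in seq_len(nrow(bt))) {
      p <- pars$bond[[r]]
      out <- c(out, sprintf("%4d %4d %5d %10.4f %10.1f", bt[r, 1], bt[r, 2], 1L,
                            p$equilibrium, p$force_constant))
    }
  }
  at <- topology$angle_terms
  if (nrow(at) > 0) {
    out <- c(out, "", "[ angles ]", ";  i    j    k funct        th0        cth")
    for (r in seq_len(nrow(at))) {
      p <- pars$angle[[r]]
      out <- c(out, sprintf("%4d %4d %4d %5d %10.3f %10.2f", at[r, 1], at[r, 2],
                            at[r, 3], 2L, p$equilibrium, p$force_constant))
    }
  }
  paste(out, collapse = "\n")
}

export_structured <- function(ff, topology, pars) {
  bt <- topology$bond_terms
  bonds <- lapply(seq_len(nrow(bt)), function(r) {
    p <- pars$bond[[r]]
    list(i = bt[r, 1], j = bt[r, 2], b0 = p$equilibrium, kb = p$force_constant)
  })
  at <- topology$angle_terms
  angles <- lapply(seq_len(nrow(at)), function(r) {
    p <- pars$angle[[r]]
    list(i = at[r, 1], j = at[r, 2], k = at[r, 3],
         th0 = p$equilibrium, cth = p$force_constant)
  })
  pairs <- NULL
  if (!is.null(ff$pair_params)) {
    pairs <- lapply(names(ff$pair_params), function(k) {
      ab <- strsplit(k, ":", fixed = TRUE)[[1]]
      list(type_a = ab[1], type_b = ab[2],
           epsilon = ff$pair_params[[k]]$epsilon,
           sigma = ff$pair_params[[k]]$sigma)
    })
  }
  doc <- list(format = "cgstack-forcefield", version = 1L, cutoff = ff$cutoff,
              bonds = bonds, angles = angles)
  if (!is.null(pairs)) doc$pairs <- pairs
  # 17 significant digits: doubles survive the round trip bit-exactly
  as.character(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = I(17),
                                pretty = TRUE))
}

#' Import force-field parameters
#'
#' Reads either the structured JSON dialect written by [export_parameters()]
#' (lossless) or the ITP-like bonded sections (to the printed precision).
#'
#' @param path path to a parameter file, or the text itself.
#' @param format `"structured"` or `"itp"`; guessed from content when `NULL`.
#' @return a [force_field()].
#' @export
import_parameters <- function(path, format = NULL) {
  txt <- if (length(path) == 1 && file.exists(path))
    paste(readLines(path, warn = FALSE), collapse = "\n") else
    paste(path, collapse = "\n")
  if (is.null(format))
    format <- if (grepl("cgstack-forcefield", txt, fixed = TRUE)) "structured"
              else "itp"
  format <- match.arg(format, c("structured", "itp"))
  if (format == "structured") import_structured(txt) else import_itp(txt)
}

import_structured <- function(txt) {
  doc <- jsonlite::fromJSON(txt, simplifyVector = FALSE)
  .assert(identical(doc$format, "cgstack-forcefield"),
          "not a cgstack structured parameter document")
  bp <- list(); ap <- list()
  # as.numeric throughout: JSON integers must come back as doubles
  for (b in doc$bonds)
    bp[[bond_key(b$i, b$j)]] <- harmonic_params(as.numeric(b$b0),
                                                as.numeric(b$kb), "bond")
  for (a in doc$angles)
    ap[[angle_key(a$i, a$j, a$k)]] <- harmonic_params(as.numeric(a$th0),
                                                      as.numeric(a$cth), "angle")
  pp <- NULL
  if (!is.null(doc$pairs)) {
    pp <- list()
    for (p in doc$pairs)
      pp[[pair_key(p$type_a, p$type_b)]] <- list(epsilon = as.numeric(p$epsilon),
                                                 sigma = as.numeric(p$sigma))
  }
  force_field(bp, ap, pair_params = pp,
              cutoff = if (is.null(doc$cutoff)) 1.1 else as.numeric(doc$cutoff))
}

import_itp <- function(txt) {
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
  lines <- sub(";.*$", "", lines)
  section <- ""
  bp <- list(); ap <- list()
  for (i in seq_along(lines)) {
    l <- trimws(lines[i])
    if (!nzchar(l)) next
    m <- regmatches(l, regexec("^\\[\\s*(\\w+)\\s*\\]$", l))[[1]]
    if (length(m) == 2) { section <- tolower(m[2]); next }
    tok <- strsplit(l, "[[:space:]]+")[[1]]
    if (section == "bonds") {
      .assert(length(tok) >= 5, "ITP line %d: malformed bond entry", i)
      v <- as.numeric(tok)
      .assert(v[3] == 1, "ITP line %d: only funct 1 (harmonic) bonds supported", i)
      bp[[bond_key(v[1], v[2])]] <- harmonic_params(v[4], v[5], "bond")
    } else if (section == "angles") {
      .assert(length(tok) >= 6, "ITP line %d: malformed angle entry", i)
      v <- as.numeric(tok)
      .assert(v[4] == 2, "ITP line %d: only funct 2 (harmonic) angles supported", i)
      ap[[angle_key(v[1], v[2], v[3])]] <- harmonic_params(v[5], v[6], "angle")
    }
  }
  force_field(bp, ap)
}
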