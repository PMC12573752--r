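#' @title Geometry and volumetric I/O
#' @description Extended-XYZ geometries (Angstrom in files, bohr internally,
#'   with a lattice line and per-atom fragment/role columns) and Gaussian
#'   cube export for scalar fields.
#' @name io
NULL

#' Construct a geometry object
#'
#' @param elements character vector of element symbols
#' @param positions n x 3 matrix of cartesian positions in bohr
#' @param cell `dfq_cell` or NULL
#' @param fragment integer vector: molecule id per atom
#' @param role character vector per atom: "QM" or "MM"
#' @return object of class `dfq_geometry`
#' @export
geometry <- function(elements, positions, cell = NULL,
                     fragment = NULL, role = NULL) {
  positions <- matrix(positions, ncol = 3)
  n <- length(elements)
  stopifnot(nrow(positions) == n)
  if (is.null(fragment)) fragment <- rep(1L, n)
  if (is.null(role)) role <- rep("QM", n)
  stopifnot(length(fragment) == n, length(role) == n,
            all(role %in% c("QM", "MM")))
  structure(list(elements = elements, positions = positions, cell = cell,
                 fragment = as.integer(fragment), role = role),
            class = "dfq_geometry")
}

#' @export
print.dfq_geometry <- function(x, ...) {
  nf <- length(unique(x$fragment))
  cat(sprintf("dfq_geometry: %d atoms, %d fragments (%s)\n",
              length(x$elements), nf, qm_mm_label(x)))
  invisible(x)
}

#' n/m partition label of a geometry
#'
#' Counts QM and MM fragments and formats them as "n/m" (n molecules at the
#' QM level, m at the MM level).
#'
#' @param geom `dfq_geometry`
#' @return character scalar like "1/63"
#' @export
qm_mm_label <- function(geom) {
  fr <- split(geom$role, geom$fragment)
  roles <- vapply(fr, function(r) r[1], character(1))
  sprintf("%d/%d", sum(roles == "QM"), sum(roles == "MM"))
}

#' Write an extended-XYZ file
#'
#' Positions are written in Angstrom; the comment line carries the lattice
#' (Angstrom) and the property layout, each atom line carries
#' element, x, y, z, fragment id and role.
#'
#' @param geom `dfq_geometry`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_xyz <- function(geom, path) {
  n <- length(geom$elements)
  lat <- ""
  if (!is.null(geom$cell)) {
    lv <- bohr_to_ang(as.vector(t(geom$cell$lattice)))
    lat <- sprintf('Lattice="%s" ', paste(sprintf("%.10f", lv), collapse = " "))
  }
  props <- 'Properties=species:S:1:pos:R:3:fragment:I:1:role:S:1'
  lines <- c(as.character(n), paste0(lat, props))
  pa <- bohr_to_ang(geom$positions)
  for (i in seq_len(n)) {
    lines <- c(lines, sprintf("%-2s %18.10f %18.10f %18.10f %6d %s",
                              geom$elements[i], pa[i, 1], pa[i, 2], pa[i, 3],
                              geom$fragment[i], geom$role[i]))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read an extended-XYZ file
#'
#' @param path input file
#' @return `dfq_geometry` (positions in bohr)
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2) stop("malformed XYZ: fewer than 2 lines")
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n) || n < 1)
    stop("malformed XYZ at line 1: bad atom count '", lines[1], "'")
  if (length(lines) < n + 2)
    stop("malformed XYZ: header declares ", n, " atoms but file has ",
         length(lines) - 2, " atom lines")
  cell <- NULL
  m <- regmatches(lines[2], regexec('Lattice="([^"]+)"', lines[2]))[[1]]
  if (length(m) == 2) {
    lv <- as.numeric(strsplit(trimws(m[2]), "\\s+")[[1]])
    if (length(lv) != 9 || any(is.na(lv)))
      stop("malformed XYZ at line 2: Lattice needs 9 numbers")
    cell <- simulation_cell(ang_to_bohr(matrix(lv, 3, 3, byrow = TRUE)))
  }
  el <- character(n); pos <- matrix(0, n, 3)
  frag <- rep(1L, n); role <- rep("QM", n)
  for (i in seq_len(n)) {
    ln <- i + 2L
    tok <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
    if (length(tok) < 4)
      stop("malformed XYZ at line ", ln, ": need element + 3 coordinates")
    if (!grepl("^[A-Z][a-z]?$", tok[1]))
      stop("malformed XYZ at line ", ln, ": unknown element '", tok[1], "'")
    xyz <- suppressWarnings(as.numeric(tok[2:4]))
    if (any(is.na(xyz)))
      stop("malformed XYZ at line ", ln, ": non-numeric coordinate")
    el[i] <- tok[1]; pos[i, ] <- ang_to_bohr(xyz)
    if (length(tok) >= 5) frag[i] <- as.integer(tok[5])
    if (length(tok) >= 6) role[i] <- tok[6]
  }
  geometry(el, pos, cell, frag, role)
}

#' Write a scalar field as a Gaussian cube file
#'
#' Standard cube layout: header in bohr, voxel vectors along the lattice,
#' values in Z-fastest order.  The sum of values times the voxel volume
#' equals `integrate_field(field)`.
#'
#' @param field `dfq_field`
#' @param geom `dfq_geometry` or NULL for an empty atom list
#' @param path output file
#' @return `path`, invisibly
#' @export
write_cube <- function(field, geom = NULL, path) {
  g <- field$grid
  natoms <- if (is.null(geom)) 0L else length(geom$elements)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("dfqmmm scalar field",
               "cube: all lengths in bohr, Z-fastest value order"), con)
  writeLines(sprintf("%5d %12.6f %12.6f %12.6f", natoms, 0, 0, 0), con)
  for (ax in 1:3) {
    v <- g$cell$lattice[ax, ] / g$shape[ax]
    writeLines(sprintf("%5d %12.6f %12.6f %12.6f", g$shape[ax],
                       v[1], v[2], v[3]), con)
  }
  if (natoms > 0) {
    for (i in seq_len(natoms)) {
      z <- element_defaults(geom$elements[i])$Z
      p <- geom$positions[i, ]
      writeLines(sprintf("%5d %12.6f %12.6f %12.6f %12.6f", z, as.numeric(z),
                         p[1], p[2], p[3]), con)
    }
  }
  vals <- field$values
  for (i in seq_len(g$shape[1])) {
    for (j in seq_len(g$shape[2])) {
      row <- vals[i, j, ]
      for (k0 in seq(1, length(row), by = 6)) {
        writeLines(paste(sprintf("%13.5e", row[k0:min(k0 + 5, length(row))]),
                         collapse = " "), con)
      }
    }
  }
  invisible(path)
}

#' Read a run configuration file
#'
#' YAML with sections `system`, `grid`, `functionals`, `mm_model`, `scf`,
#' `output`; missing sections fall back to package defaults.
#'
#' @param path YAML file
#' @return named list
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("config is not a YAML mapping: ", path)
  cfg
}
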