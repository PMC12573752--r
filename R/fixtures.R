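#' @title Synthetic geometry generators
#' @description Rigid-water fixtures standing in for external datasets: a
#'   hydrogen-bonded dimer scan, random periodic water boxes, an idealized
#'   prism-like hexamer with full QM/MM partition enumeration, and pentamer
#'   (first-solvation-shell) clusters.  All generators are deterministic
#'   given their arguments (and seed, where one applies).
#' @name fixtures
NULL

# rigid gas-phase water monomer in its molecular frame: O at the origin,
# bisector along +z, H atoms in the xz-plane.  r(OH) = 0.9572 A, 104.52 deg.
.water_template <- function() {
  r <- ang_to_bohr(0.9572)
  th <- 104.52 * pi / 180
  rbind(O = c(0, 0, 0),
        H1 = c(r * sin(th / 2), 0, r * cos(th / 2)),
        H2 = c(-r * sin(th / 2), 0, r * cos(th / 2)))
}

# rotation matrix from a unit quaternion
.quat_rot <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# rotation taking unit vector a to unit vector b
.align_rot <- function(a, b) {
  a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  v <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  c0 <- sum(a * b)
  if (c0 > 1 - 1e-12) return(diag(3))
  if (c0 < -1 + 1e-12) {
    p <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    v <- p - sum(p * a) * a; v <- v / sqrt(sum(v^2))
    return(2 * outer(v, v) - diag(3))
  }
  K <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + K + K %*% K / (1 + c0)
}

# one water monomer: rotation matrix applied in the molecular frame, then
# translated so O sits at `origin` (bohr)
.place_water <- function(origin, rot = diag(3)) {
  tpl <- .water_template()
  sweep(tpl %*% t(rot), 2, origin, `+`)
}

#' Generate a rigid water dimer scan
#'
#' Hydrogen-bonded donor/acceptor arrangement: the donor's O-H1 bond points
#' along the O-O axis toward the acceptor oxygen; the acceptor's bisector
#' points away from the donor.  One geometry per evenly spaced O-O distance.
#'
#' @param r_min,r_max O-O distance range in Angstrom (defaults 2.3 to 7.7)
#' @param n_points number of scan points
#' @param cell_edge cubic cell edge in Angstrom
#' @param swap_labels if TRUE the donor is tagged MM and the acceptor QM
#'   (the mirrored labeling for the consistency test); default donor = QM
#' @return list of `dfq_geometry`, each with fragments 1 (donor) and 2
#'   (acceptor)
#' @export
generate_dimer_scan <- function(r_min = 2.3, r_max = 7.7, n_points = 10,
                                cell_edge = 20, swap_labels = FALSE) {
  stopifnot(r_min <= r_max, n_points >= 1)
  dists <- if (n_points == 1) r_min else seq(r_min, r_max, length.out = n_points)
  cell <- simulation_cell(ang_to_bohr(cell_edge))
  ctr <- ang_to_bohr(cell_edge) / 2
  # donor: rotate so the O-H1 bond points along +x
  tpl <- .water_template()
  rot_d <- .align_rot(tpl["H1", ] - tpl["O", ], c(1, 0, 0))
  # acceptor: bisector (+z in template) pointing along +x, then tilted
  rot_a <- .align_rot(c(0, 0, 1), c(1, 0, 0))
  tilt <- 55 * pi / 180   # acceptor tilt out of the O-O axis
  rot_a <- .quat_rot(c(cos(tilt / 2), 0, sin(tilt / 2), 0)) %*% rot_a
  roles <- if (swap_labels) c("MM", "QM") else c("QM", "MM")
  lapply(dists, function(d) {
    db <- ang_to_bohr(d)
    don <- .place_water(c(ctr - db / 2, ctr, ctr), rot_d)
    acc <- .place_water(c(ctr + db / 2, ctr, ctr), rot_a)
    geometry(rep(c("O", "H", "H"), 2), rbind(don, acc), cell,
             fragment = rep(1:2, each = 3),
             role = rep(roles, each = 3))
  })
}

#' Generate a centrosymmetric water dimer
#'
#' Two identical rigid monomers related by inversion through the cell
#' center, which maps the simulation grid onto itself exactly.  Swapping
#' the QM/MM labels of the two fragments is therefore an exact symmetry of
#' the model, useful for consistency tests.
#'
#' @param separation O-O distance in Angstrom
#' @param cell_edge cubic cell edge in Angstrom
#' @return `dfq_geometry` with fragments 1 (QM) and 2 (MM)
#' @export
generate_symmetric_dimer <- function(separation = 3.0, cell_edge = 8.5) {
  cell <- simulation_cell(ang_to_bohr(cell_edge))
  ctr <- rep(ang_to_bohr(cell_edge) / 2, 3)
  half <- ang_to_bohr(separation) / 2
  rot <- .quat_rot(c(0.88, 0.27, 0.36, 0.13))   # fixed generic orientation
  a <- .place_water(ctr + c(-half, 0, 0), rot)
  b <- sweep(-a, 2, 2 * ctr, `+`)               # inversion image
  geometry(rep(c("O", "H", "H"), 2), rbind(a, b), cell,
           fragment = rep(1:2, each = 3), role = rep(c("QM", "MM"), each = 3))
}

#' Generate a random periodic water box
#'
#' Seeded rejection-sampled packing of rigid water molecules with random
#' orientations; every intermolecular O-O distance (minimum image) is kept
#' at or above `min_oo` Angstrom.  Deterministic for a given seed.
#'
#' @param n_molecules number of waters
#' @param box_edge cubic cell edge in Angstrom (default the 64-molecule
#'   bulk cell, 12.42 A)
#' @param seed RNG seed
#' @param min_oo minimum O-O contact distance in Angstrom
#' @param max_attempts placement attempts per molecule before giving up
#' @return `dfq_geometry`, all fragments tagged MM
#' @export
generate_water_box <- function(n_molecules = 64, box_edge = 12.42, seed = 1,
                               min_oo = 2.4, max_attempts = 5000) {
  cell <- simulation_cell(ang_to_bohr(box_edge))
  L <- ang_to_bohr(box_edge)
  dmin <- ang_to_bohr(min_oo)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  centers <- matrix(0, 0, 3)
  pos <- NULL; el <- character(0)
  for (m in seq_len(n_molecules)) {
    placed <- FALSE
    for (a in seq_len(max_attempts)) {
      o <- stats::runif(3, 0, L)
      if (nrow(centers) > 0) {
        dr <- .min_image(cell, sweep(centers, 2, o, `-`))
        if (min(sqrt(rowSums(dr^2))) < dmin) next
      }
      rot <- .quat_rot(stats::rnorm(4))
      pos <- rbind(pos, .place_water(o, rot))
      centers <- rbind(centers, o)
      el <- c(el, "O", "H", "H")
      placed <- TRUE
      break
    }
    if (!placed)
      stop("packing failure: could not place molecule ", m, " of ",
           n_molecules, " after ", max_attempts, " attempts")
  }
  geometry(el, pos, cell, fragment = rep(seq_len(n_molecules), each = 3),
           role = rep("MM", 3 * n_molecules))
}

#' Generate an idealized water cluster
#'
#' `"pentamer"`: one central molecule surrounded by four neighbors at the
#' tetrahedral directions (the first-solvation-shell motif); the central
#' molecule is fragment 1.  `"hexamer"`: a prism-like cluster of six
#' molecules on two stacked triangles.  Geometries are idealized
#' hydrogen-bonded motifs, not literature coordinates.
#'
#' @param kind "pentamer" or "hexamer"
#' @param oo_dist nearest-neighbor O-O distance in Angstrom
#' @param cell_edge cubic cell edge in Angstrom
#' @return `dfq_geometry` (all molecules tagged QM; use
#'   `set_partition_roles` to assign QM/MM splits)
#' @export
generate_cluster <- function(kind = c("pentamer", "hexamer"), oo_dist = 2.8,
                             cell_edge = 14) {
  kind <- match.arg(kind)
  cell <- simulation_cell(ang_to_bohr(cell_edge))
  ctr <- rep(ang_to_bohr(cell_edge) / 2, 3)
  d <- ang_to_bohr(oo_dist)
  if (kind == "pentamer") {
    dirs <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) /
      sqrt(3)
    centers <- rbind(c(0, 0, 0), d * dirs)
  } else {
    s <- d / sqrt(3)   # circumradius of the triangle with side d
    tri <- rbind(c(s, 0, 0),
                 c(-s / 2, s * sqrt(3) / 2, 0),
                 c(-s / 2, -s * sqrt(3) / 2, 0))
    centers <- rbind(sweep(tri, 2, c(0, 0, -d / 2), `+`),
                     sweep(tri, 2, c(0, 0, d / 2), `+`))
  }
  centers <- sweep(centers, 2, ctr, `+`)
  cen <- colMeans(centers)
  pos <- NULL
  for (i in seq_len(nrow(centers))) {
    out <- centers[i, ] - cen
    rot <- if (sqrt(sum(out^2)) < 1e-9) diag(3) else
      .align_rot(c(0, 0, 1), out)   # bisector pointing outward
    pos <- rbind(pos, .place_water(centers[i, ], rot))
  }
  n <- nrow(centers)
  geometry(rep(c("O", "H", "H"), n), pos, cell,
           fragment = rep(seq_len(n), each = 3), role = rep("QM", 3 * n))
}

#' Enumerate QM/MM partitions of a cluster
#'
#' For a cluster of n molecules and a given k, emits all choose(n, k)
#' assignments with k molecules QM and n - k molecules MM.
#'
#' @param geom `dfq_geometry` with one fragment per molecule
#' @param k number of QM molecules
#' @return list of `dfq_geometry`, length choose(n, k)
#' @export
enumerate_partitions <- function(geom, k) {
  frs <- sort(unique(geom$fragment))
  n <- length(frs)
  stopifnot(k >= 0, k <= n)
  if (k == 0) return(list(set_partition_roles(geom, integer(0))))
  combos <- utils::combn(frs, k, simplify = FALSE)
  lapply(combos, function(qm) set_partition_roles(geom, qm))
}

#' Assign QM/MM roles by fragment
#'
#' @param geom `dfq_geometry`
#' @param qm_fragments fragment ids to promote to QM; all others become MM
#' @return `dfq_geometry`
#' @export
set_partition_roles <- function(geom, qm_fragments) {
  geom$role <- ifelse(geom$fragment %in% qm_fragments, "QM", "MM")
  geom
}

#' Enumerate the bulk single-molecule interaction tasks
#'
#' The bulk calibration protocol evaluates, for each of `n_boxes` water
#' boxes and each molecule in the box, the interaction energy of that one
#' molecule (QM) with its environment (MM): `n_boxes * n_molecules` tasks.
#'
#' @param n_boxes number of box snapshots (default 10)
#' @param n_molecules molecules per box (default 64)
#' @param box_edge cubic cell edge in Angstrom
#' @param seeds RNG seed per box (default 1..n_boxes)
#' @return data.frame with columns `box`, `seed`, `molecule`
#' @export
enumerate_bulk_tasks <- function(n_boxes = 10, n_molecules = 64,
                                 box_edge = 12.42, seeds = seq_len(n_boxes)) {
  stopifnot(length(seeds) == n_boxes)
  data.frame(box = rep(seq_len(n_boxes), each = n_molecules),
             seed = rep(seeds, each = n_molecules),
             molecule = rep(seq_len(n_molecules), times = n_boxes))
}
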