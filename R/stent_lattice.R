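# Geometric realization of a ring-and-link stent design on a cylinder:
# zigzag rings of alternating peaks and valleys, adjacent rings joined by
# axial links, with purely kinematic expansion (inextensible struts).
#
# Coordinate convention: cylindrical, theta in [0, 2*pi) right-handed,
# z along the stent axis in mm with z = 0 at the proximal edge, r in mm
# measured to the strut centerline.

#' Build the lattice of a stent design at its crimped state
#'
#' Rings are zigzags of 2*peaks straight strut legs between alternating
#' peak and valley nodes; adjacent rings are mirrored so crowns face each
#' other, and axial links of length `link_gap` join facing crowns at the
#' positions prescribed by the design's link distribution (evenly spread
#' around the circumference with a rotational offset per ring pair).
#'
#' @param design A [stent_design()].
#' @return An object of class `stent_lattice` with fields:
#'   `theta`, `z`, `r` (node coordinates), `ring` (ring membership),
#'   `edges` (2-column matrix of node indices), `edge_type`
#'   (`"strut"`/`"link"`), `leg_length` (strut leg length, preserved under
#'   expansion), `crown_height` (current axial ring extent) and `design`.
#' @export
build_lattice <- function(design) {
  stopifnot(inherits(design, "stent_design"))
  p <- design$peaks; R <- design$rings
  h <- design$crown_height; g <- design$link_gap
  r0 <- (design$crimped_id + design$strut_thickness) / 2
  n_per_ring <- 2L * p
  m <- seq_len(n_per_ring) - 1L

  theta <- numeric(0); z <- numeric(0); ring <- integer(0)
  z_base <- 0
  for (k in seq_len(R)) {
    up <- (k %% 2L == 1L)  # odd rings peak distally, even rings mirrored
    zz <- if (up) z_base + h * (m %% 2L) else z_base + h * (1L - m %% 2L)
    theta <- c(theta, pi * m / p)
    z <- c(z, zz)
    ring <- c(ring, rep(k, n_per_ring))
    z_base <- z_base + h + g
  }
  node_id <- function(k, mm) (k - 1L) * n_per_ring + mm + 1L

  # ring struts: consecutive nodes around each ring
  e_from <- integer(0); e_to <- integer(0)
  for (k in seq_len(R)) {
    e_from <- c(e_from, node_id(k, m))
    e_to <- c(e_to, node_id(k, c(m[-1], 0L)))
  }
  type <- rep("strut", length(e_from))

  # links: facing crowns of adjacent rings share a theta position; the
  # parity of those crown node indices alternates with the ring pair
  for (k in seq_len(R - 1L)) {
    nk <- design$links_per_pair[k]
    parity <- if (k %% 2L == 1L) 1L else 0L
    crowns <- m[m %% 2L == parity]        # p candidate crown indices
    offset <- (k - 1L) %% p
    pick <- crowns[(floor((seq_len(nk) - 1L) * p / nk) + offset) %% p + 1L]
    e_from <- c(e_from, node_id(k, pick))
    e_to <- c(e_to, node_id(k + 1L, pick))
    type <- c(type, rep("link", nk))
  }

  chord0 <- 2 * r0 * sin(pi / (2 * p))
  lat <- list(
    theta = theta, z = z, r = rep(r0, length(theta)), ring = ring,
    edges = cbind(e_from, e_to), edge_type = type,
    leg_length = sqrt(h^2 + chord0^2), crown_height = h,
    design = design
  )
  class(lat) <- "stent_lattice"
  lat
}

#' @export
print.stent_lattice <- function(x, ...) {
  cat(sprintf("<stent_lattice> %s: %d nodes, %d edges, radius %.3f mm, length %.3f mm\n",
              x$design$name, length(x$theta), nrow(x$edges),
              x$r[1], lattice_length(x)))
  invisible(x)
}

#' Axial length of a lattice (z extent)
#' @param lattice A [build_lattice()] result.
#' @return Length in mm.
#' @export
lattice_length <- function(lattice) {
  max(lattice$z) - min(lattice$z)
}

# breadth-first connectivity check on the lattice graph
.lattice_connected <- function(lattice) {
  n <- length(lattice$theta)
  adj <- vector("list", n)
  for (e in seq_len(nrow(lattice$edges))) {
    a <- lattice$edges[e, 1]; b <- lattice$edges[e, 2]
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
  }
  seen <- logical(n); queue <- 1L; seen[1] <- TRUE
  while (length(queue) > 0) {
    v <- queue[1]; queue <- queue[-1]
    nb <- adj[[v]]; new <- nb[!seen[nb]]
    seen[new] <- TRUE; queue <- c(queue, new)
  }
  all(seen)
}

#' Maximum kinematically reachable inner diameter of a design
#'
#' The zigzag rings straighten as the stent expands; with inextensible
#' strut legs the circumference saturates when the legs lie fully in the
#' circumferential plane, at centerline radius
#' \eqn{r_{max} = L / (2 \sin(\pi / 2p))}.
#'
#' @param design A [stent_design()].
#' @return Maximum inner diameter in mm.
#' @export
max_expansion_diameter <- function(design) {
  lat <- build_lattice(design)
  r_max <- lat$leg_length / (2 * sin(pi / (2 * design$peaks)))
  2 * r_max - design$strut_thickness
}

#' Kinematic expansion of a lattice to a target inner diameter
#'
#' Maps all nodes to the target radius keeping every strut leg length
#' fixed: the crown opening angle increases and the axial extent of each
#' ring shrinks (foreshortening). Node angular positions are unchanged.
#'
#' @param lattice A [build_lattice()] result.
#' @param target_id Target inner diameter in mm (>= crimped inner diameter).
#' @return The deformed `stent_lattice`.
#' @export
expand_kinematics <- function(lattice, target_id) {
  stopifnot(inherits(lattice, "stent_lattice"))
  d <- lattice$design
  if (target_id < d$crimped_id - 1e-12) {
    stop("target diameter below the crimped inner diameter")
  }
  r_new <- target_id / 2 + d$strut_thickness / 2
  chord <- 2 * r_new * sin(pi / (2 * d$peaks))
  if (chord > lattice$leg_length) {
    stop(sprintf(
      "target inner diameter %.3f mm unreachable; maximum reachable is %.3f mm",
      target_id, max_expansion_diameter(d)))
  }
  h_new <- sqrt(lattice$leg_length^2 - chord^2)
  h_old <- lattice$crown_height
  p <- d$peaks; R <- d$rings; n_per_ring <- 2L * p
  z <- lattice$z
  for (k in seq_len(R)) {
    idx <- which(lattice$ring == k)
    z_base_old <- (k - 1L) * (h_old + d$link_gap)
    z_base_new <- (k - 1L) * (h_new + d$link_gap)
    # node height within the ring rescales with the crown height
    z[idx] <- z_base_new + (lattice$z[idx] - z_base_old) * (h_new / h_old)
  }
  out <- lattice
  out$z <- z
  out$r <- rep(r_new, length(lattice$r))
  out$crown_height <- h_new
  out
}

# 3-D cartesian coordinates of the lattice nodes
.lattice_xyz <- function(lattice) {
  cbind(x = lattice$r * cos(lattice$theta),
        y = lattice$r * sin(lattice$theta),
        z = lattice$z)
}

#' Lengths of all lattice segments (3-D chord lengths)
#' @param lattice A [build_lattice()] result.
#' @return Numeric vector, one length per edge, in mm.
#' @export
segment_lengths <- function(lattice) {
  xyz <- .lattice_xyz(lattice)
  a <- lattice$edges[, 1]; b <- lattice$edges[, 2]
  sqrt(rowSums((xyz[a, , drop = FALSE] - xyz[b, , drop = FALSE])^2))
}

#' Outer surface area of the stent struts
#'
#' Sum over all segments of segment length times strut width: the
#' footprint of the strut outer faces on the lumen.
#'
#' @param lattice A [build_lattice()] result (crimped or deformed).
#' @param design The [stent_design()]; defaults to the lattice's own.
#' @return Area in mm^2.
#' @export
strut_outer_surface_area <- function(lattice, design = lattice$design) {
  sum(segment_lengths(lattice)) * design$strut_width
}

# wrapped angular difference in (-pi, pi]
.wrap_dtheta <- function(dth) {
  ((dth + pi) %% (2 * pi)) - pi
}

# Combinatorial face extraction of the lattice graph embedded on its
# cylinder. Returns, for each face, the ordered node index loop. The two
# faces that wind around the cylinder (the proximal and distal end faces)
# are discarded; interior faces have zero total theta winding. Results
# depend only on the design's combinatorics, so callers may cache per
# design name.
.lattice_faces <- function(lattice) {
  if (!.lattice_connected(lattice)) stop("lattice graph is disconnected")
  n <- length(lattice$theta)
  ed <- lattice$edges
  m <- nrow(ed)
  # directed edges: 1..m are a->b, m+1..2m are b->a
  from <- c(ed[, 1], ed[, 2]); to <- c(ed[, 2], ed[, 1])
  rev_of <- c(m + seq_len(m), seq_len(m))
  dth <- .wrap_dtheta(lattice$theta[to] - lattice$theta[from])
  dx <- lattice$r[from] * dth
  dz <- lattice$z[to] - lattice$z[from]
  ang <- atan2(dz, dx)

  nxt <- integer(2 * m)
  for (v in seq_len(n)) {
    out_ids <- which(from == v)
    ord <- out_ids[order(ang[out_ids])]     # counterclockwise at v
    deg <- length(ord)
    pos <- match(ord, ord)
    # successor of directed edge e=(u->v): the outgoing edge at v that is
    # the next one clockwise from the reversal (v->u)
    for (q in seq_len(deg)) {
      e_out <- ord[q]
      prev_ccw <- ord[if (q == 1) deg else q - 1]
      nxt[rev_of[e_out]] <- prev_ccw
    }
  }

  used <- logical(2 * m)
  faces <- list(); windings <- numeric(0)
  for (e0 in seq_len(2 * m)) {
    if (used[e0]) next
    loop_nodes <- integer(0); wind <- 0
    e <- e0
    repeat {
      used[e] <- TRUE
      loop_nodes <- c(loop_nodes, from[e])
      wind <- wind + dth[e]
      e <- nxt[e]
      if (e == e0) break
    }
    faces[[length(faces) + 1]] <- loop_nodes
    windings <- c(windings, wind)
  }
  interior <- abs(windings) < pi  # end faces wind +-2*pi
  faces[interior]
}

# per-design cache of the combinatorial face loops
.face_cache <- new.env(parent = emptyenv())

#' Closed cell boundary loops of a stent lattice
#'
#' Extracts every interior face (stent cell) of the lattice graph embedded
#' on its cylinder, via the combinatorial embedding induced by the node
#' angular order. Each cell is returned exactly once as an ordered vertex
#' loop with the theta coordinate unwrapped continuously, so cells crossing
#' the theta = 0 seam are not split.
#'
#' @param lattice A [build_lattice()] result (crimped or deformed).
#' @return A list of cells; each cell is a list with `nodes` (node indices)
#'   and `coords`, a matrix with columns `theta` (unwrapped, radians),
#'   `z` (mm) and `r` (mm).
#' @export
cell_polygons <- function(lattice) {
  stopifnot(inherits(lattice, "stent_lattice"))
  d <- lattice$design
  key <- paste(d$name, d$peaks, d$rings,
               paste(d$links_per_pair, collapse = "-"), sep = "|")
  faces <- if (!is.null(key) && !is.null(.face_cache[[key]])) {
    .face_cache[[key]]
  } else {
    f <- .lattice_faces(lattice)
    if (!is.null(key)) .face_cache[[key]] <- f
    f
  }
  lapply(faces, function(loop) {
    th <- lattice$theta[loop]
    # unwrap continuously from the first vertex
    dth <- .wrap_dtheta(diff(th))
    th_unwrapped <- th[1] + c(0, cumsum(dth))
    list(nodes = loop,
         coords = cbind(theta = th_unwrapped, z = lattice$z[loop],
                        r = lattice$r[loop]))
  })
}

#' Expected interior cell count of a connected lattice on the cylinder
#'
#' By Euler's formula for the lattice graph embedded on a cylinder
#' (capping the two ends), the interior face count is `edges - vertices`.
#' Kept exported as the independent oracle for [cell_polygons()].
#'
#' @param lattice A [build_lattice()] result.
#' @return Integer cell count.
#' @export
expected_cell_count <- function(lattice) {
  nrow(lattice$edges) - length(lattice$theta)
}

#' Export a lattice as a legacy-VTK line mesh (ASCII)
#'
#' Writes nodes and strut/link segments as a `POLYDATA` line set for
#' visualization in ParaView-style tools.
#'
#' @param lattice A [build_lattice()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_lattice_vtk <- function(lattice, path) {
  xyz <- .lattice_xyz(lattice)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "stent lattice", "ASCII",
               "DATASET POLYDATA",
               sprintf("POINTS %d float", nrow(xyz))), con)
  utils::write.table(format(xyz, digits = 9, trim = TRUE), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  m <- nrow(lattice$edges)
  writeLines(sprintf("LINES %d %d", m, 3 * m), con)
  utils::write.table(cbind(2L, lattice$edges - 1L), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}
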