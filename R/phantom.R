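#' Specification of the synthetic layered abdominal-wall phantom
#'
#' The phantom is a curved rectangular slab of four stacked soft-tissue
#' strata (external oblique, internal oblique, rectus abdominis and
#' transverse abdominis analogues, outer to inner) joined by a stiff
#' vertical midline strip standing in for the linea alba. The slab is bent
#' to a cylinder of radius `curvature_radius` about the vertical axis and is
#' fixed (zero displacement) along all four lateral edges, where the real
#' musculature attaches to bone. An optional circular through-hole of
#' `hole_diameter` mm — the trephine incision — can be placed at any of 17
#' labelled positions: `"s0"` on the midline strip, and `"s{i}{j}"` on three
#' vertical lines on the left half, with lateral offset growing with `i`
#' (6, 6 and 4 vertical positions for i = 1, 2, 3).
#'
#' Generation is fully deterministic given the spec, including `seed`:
#' `seed = 0` (default) applies no node jitter, a positive seed perturbs
#' interior in-plane nodes by up to 5% of `resolution` for mesh-sensitivity
#' experiments.
#'
#' @param width,height in-plane extents in mm (arc length by height).
#' @param layer_thicknesses four thicknesses in mm, outer to inner
#'   (EO, IO, RA, TR analogues).
#' @param strip_width width of the stiff midline strip in mm.
#' @param curvature_radius bending radius of the mid-surface in mm; `Inf`
#'   gives a flat slab.
#' @param hole_position `NULL` (no trephine) or one of [stoma_position_labels()].
#' @param hole_diameter trephine diameter in mm (default 20, the 2 cm
#'   circular incision).
#' @param resolution background target edge length in mm.
#' @param circle_nodes number of mesh nodes placed exactly on the trephine
#'   circle (multiple of 8, at least 16).
#' @param rings number of radial element rings between the circle and the
#'   surrounding structured grid.
#' @param seed integer jitter seed; 0 means no jitter.
#' @return An object of class `"phantom_spec"`.
#' @export
phantom_spec <- function(width = 300, height = 400,
                         layer_thicknesses = c(3, 3, 3, 3),
                         strip_width = 20, curvature_radius = 200,
                         hole_position = NULL, hole_diameter = 20,
                         resolution = 7.5, circle_nodes = 64L,
                         rings = 6L, seed = 0L) {
  stopifnot(width > 0, height > 0, strip_width > 0, resolution > 0,
            length(layer_thicknesses) == 4L, all(layer_thicknesses > 0),
            curvature_radius > 0, hole_diameter > 0)
  circle_nodes <- as.integer(circle_nodes)
  if (circle_nodes < 16L || circle_nodes %% 8L != 0L) {
    stop("circle_nodes must be a multiple of 8 and at least 16")
  }
  spec <- structure(
    list(width = width, height = height,
         layer_thicknesses = as.double(layer_thicknesses),
         strip_width = strip_width, curvature_radius = curvature_radius,
         hole_position = hole_position, hole_diameter = hole_diameter,
         resolution = resolution, circle_nodes = circle_nodes,
         rings = as.integer(rings), seed = as.integer(seed)),
    class = "phantom_spec")
  if (!is.null(hole_position)) {
    pos <- stoma_positions(spec)
    if (!hole_position %in% pos$label) {
      stop("unknown hole position '", hole_position, "'; expected one of: ",
           paste(pos$label, collapse = ", "))
    }
    ctr <- pos[pos$label == hole_position, ]
    r <- hole_diameter / 2
    clearance <- min(ctr$x + width / 2, width / 2 - ctr$x, ctr$y, height - ctr$y) - r
    if (hole_diameter >= clearance) {
      stop("hole at '", hole_position,
           "' is too close to the fixed boundary (clearance ",
           format(clearance, digits = 4), " mm < diameter)")
    }
  }
  spec
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("<phantom_spec> %g x %g x %g mm wall, strip %g mm, Rc = %g mm, %s\n",
              x$width, x$height, sum(x$layer_thicknesses), x$strip_width,
              x$curvature_radius,
              if (is.null(x$hole_position)) "no trephine" else
                sprintf("trephine %g mm at %s", x$hole_diameter, x$hole_position)))
  invisible(x)
}

#' The 17 labelled stoma positions on the phantom
#'
#' `"s0"` sits on the midline strip at mid-height. The lateral positions
#' `"s{i}{j}"` lie on three vertical lines on the left half of the wall at
#' 10%, 23.3% and 36.7% of the width from the midline, with 6, 6 and 4
#' vertical stations; height grows with `j`. Coordinates are in the
#' developed (unrolled) plane of the wall, midline at x = 0.
#'
#' @param spec a [phantom_spec()]; positions scale with its width/height.
#' @return A tibble with columns `label`, `i`, `j`, `x`, `y` (mm).
#' @export
stoma_positions <- function(spec = phantom_spec()) {
  xfrac <- c(0.10, 0.7 / 3, 1.1 / 3)
  yfrac_16 <- (2 * (1:6) + 1) / 16      # 0.1875 .. 0.8125
  yfrac_34 <- c(0.275, 0.425, 0.575, 0.725)
  rows <- list(tibble::tibble(label = "s0", i = 0L, j = 0L,
                              x = 0, y = spec$height / 2))
  for (i in 1:3) {
    jj <- if (i < 3) 1:6 else 1:4
    yf <- if (i < 3) yfrac_16 else yfrac_34
    rows[[i + 1L]] <- tibble::tibble(
      label = paste0("s", i, jj), i = i, j = jj,
      x = -xfrac[i] * spec$width, y = yf * spec$height)
  }
  dplyr::bind_rows(rows)
}

#' @rdname stoma_positions
#' @export
stoma_position_labels <- function() stoma_positions()$label

# 1D graded line generator: from the fine end `a` (first spacing h0) toward
# `b`, growing geometrically to at most hmax, then uniform; hits both ends
# exactly. Returns increasing or decreasing sequence from a to b.
graded_lines <- function(a, b, h0, hmax, ratio = 1.35) {
  len <- abs(b - a)
  if (len < 1e-12) return(a)
  h <- min(h0, hmax)
  steps <- numeric(0)
  pos <- 0
  while (pos < len) {
    steps <- c(steps, h)
    pos <- pos + h
    h <- min(h * ratio, hmax)
  }
  steps <- steps * (len / sum(steps))
  out <- a + sign(b - a) * cumsum(c(0, steps))
  out[length(out)] <- b
  out
}

# merge sorted line coordinates closer than tol, keeping "protected" values
merge_lines <- function(lines, protected = numeric(0), tol = 1) {
  lines <- c(lines, protected)
  for (p in protected) lines[abs(lines - p) < 1e-7] <- p
  lines <- sort(unique(lines))
  is_prot <- vapply(lines, function(v) any(abs(v - protected) < 1e-9), TRUE)
  keep <- rep(TRUE, length(lines))
  for (i in seq_along(lines)[-1L]) {
    prev <- max(which(keep[seq_len(i - 1L)]))
    if (lines[i] - lines[prev] >= tol) next
    if (is_prot[i] && is_prot[prev]) next
    if (is_prot[i]) keep[prev] <- FALSE else keep[i] <- FALSE
  }
  lines[keep]
}

# Build the 2D in-plane mesh of the wall: tensor grid, optionally with an
# O-grid (butterfly) block carving the trephine circle. Returns
# list(points (n x 2), tris (m x 3, CCW), circle (ids of the ring nodes in
# CCW angular order, or NULL)).
wall_plane_mesh <- function(spec) {
  W <- spec$width; H <- spec$height; res <- spec$resolution
  sw2 <- spec$strip_width / 2
  hole <- !is.null(spec$hole_position)
  if (!hole) {
    xl <- c(graded_lines(-sw2, -W / 2, res, res),
            seq(-sw2, sw2, length.out = max(2L, round(spec$strip_width / res) + 1L)),
            graded_lines(sw2, W / 2, res, res))
    xl <- merge_lines(xl, protected = c(-W / 2, -sw2, sw2, W / 2), tol = res / 4)
    yl <- seq(0, H, length.out = max(2L, round(H / res) + 1L))
    nx <- length(xl); ny <- length(yl)
    pts <- cbind(rep(xl, ny), rep(yl, each = nx))
    quads <- grid_quads(nx, ny)
    qcx <- (pts[quads[, 1], 1] + pts[quads[, 3], 1]) / 2
    return(list(points = pts, tris = quads_to_tris(quads),
                tri_quad_cx = rep(qcx, 2L), circle = NULL))
  }

  ctr <- stoma_positions(spec)
  ctr <- ctr[ctr$label == spec$hole_position, ]
  cx <- ctr$x; cy <- ctr$y
  r <- spec$hole_diameter / 2
  m <- spec$circle_nodes
  R <- 2 * r                       # half-width of the O-grid window
  # ray offsets where the m uniform angles hit the window square
  koff <- seq(-m / 8, m / 8)
  off <- R * tan(2 * pi * koff / m)
  off[1] <- -R; off[length(off)] <- R      # kill tan() roundoff at 45 degrees
  h_edge <- off[2] - off[1]

  xl <- c(graded_lines(cx - R, -W / 2, h_edge, res), cx + off,
          graded_lines(cx + R, W / 2, h_edge, res))
  yl <- c(graded_lines(cy - R, 0, h_edge, res), cy + off,
          graded_lines(cy + R, H, h_edge, res))
  prot_x <- c(-W / 2, W / 2, cx + off)
  if (-sw2 < cx - R - 1e-9 || -sw2 > cx + R + 1e-9) prot_x <- c(prot_x, -sw2)
  if (sw2 < cx - R - 1e-9 || sw2 > cx + R + 1e-9) prot_x <- c(prot_x, sw2)
  xl <- merge_lines(xl, protected = prot_x, tol = min(res, h_edge) / 3)
  yl <- merge_lines(yl, protected = c(0, H, cy + off), tol = min(res, h_edge) / 3)

  nx <- length(xl); ny <- length(yl)
  pts <- cbind(rep(xl, ny), rep(yl, each = nx))
  inside_win <- function(p, tolw = 1e-9) {
    abs(p[, 1] - cx) < R - tolw & abs(p[, 2] - cy) < R - tolw
  }
  keep_node <- !inside_win(pts)
  new_id <- cumsum(keep_node)            # tensor node -> kept id
  quads <- grid_quads(nx, ny)
  qc <- cbind((pts[quads[, 1], 1] + pts[quads[, 3], 1]) / 2,
              (pts[quads[, 1], 2] + pts[quads[, 3], 2]) / 2)
  keep_quad <- !inside_win(qc, tolw = -1e-9)
  quads <- quads[keep_quad, , drop = FALSE]
  if (!all(keep_node[quads])) stop("internal error: kept quad uses removed node")
  quads[] <- new_id[quads]
  points2 <- pts[keep_node, , drop = FALSE]
  n_tensor <- nrow(points2)

  # O-grid annulus: ring 0 on the circle, ring `rings` = window boundary
  theta <- 2 * pi * (seq_len(m) - 1L) / m
  dirx <- cos(theta); diry <- sin(theta)
  rho_sq <- R / pmax(abs(dirx), abs(diry))
  nr <- spec$rings
  w <- cumsum(c(0, 1.3^(0:(nr - 1))))
  sfrac <- w / w[length(w)]                  # 0 .. 1, geometric growth
  ann_ids <- matrix(0L, m, nr + 1L)
  ann_pts <- list()
  next_id <- n_tensor
  for (l in 0:(nr - 1L)) {
    rad <- r + sfrac[l + 1L] * (rho_sq - r)
    ann_pts[[l + 1L]] <- cbind(cx + rad * dirx, cy + rad * diry)
    ann_ids[, l + 1L] <- next_id + seq_len(m)
    next_id <- next_id + m
  }
  points2 <- rbind(points2, do.call(rbind, ann_pts))
  # outer ring: match the ray hit points to existing window-boundary nodes
  hitx <- cx + rho_sq * dirx
  hity <- cy + rho_sq * diry
  on_edge <- which(abs(abs(points2[seq_len(n_tensor), 1] - cx) - R) < 1e-7 |
                   abs(abs(points2[seq_len(n_tensor), 2] - cy) - R) < 1e-7)
  for (k in seq_len(m)) {
    d2 <- (points2[on_edge, 1] - hitx[k])^2 + (points2[on_edge, 2] - hity[k])^2
    jmin <- which.min(d2)
    if (d2[jmin] > 1e-10) stop("internal error: O-grid/tensor interface mismatch")
    ann_ids[k, nr + 1L] <- on_edge[jmin]
  }
  kk <- seq_len(m); kn <- c(2:m, 1L)
  ann_quads <- do.call(rbind, lapply(seq_len(nr), function(l) {
    cbind(ann_ids[kk, l], ann_ids[kk, l + 1L], ann_ids[kn, l + 1L], ann_ids[kn, l])
  }))
  all_quads <- rbind(quads, ann_quads)
  qcx <- (points2[all_quads[, 1], 1] + points2[all_quads[, 2], 1] +
          points2[all_quads[, 3], 1] + points2[all_quads[, 4], 1]) / 4
  list(points = points2, tris = quads_to_tris(all_quads),
       tri_quad_cx = rep(qcx, 2L), circle = as.integer(ann_ids[, 1L]))
}

#' Build the layered abdominal-wall phantom mesh
#'
#' Deterministically meshes the wall described by a [phantom_spec()] into a
#' conforming tetrahedral mesh: a graded structured grid in the plane (with
#' an O-grid block placing `circle_nodes` nodes exactly on the trephine
#' circle when a hole is requested), extruded through the four tissue
#' layers, then bent to the requested curvature by developing each
#' through-thickness sheet isometrically onto its own cylinder. The
#' development preserves in-sheet lengths, so the reference trephine loop
#' measures exactly like its flat counterpart, and preserves volume.
#'
#' Region tags: `"EO"`, `"IO"`, `"RA"`, `"TR"` for the strata (outer to
#' inner) and `"LA"` for the full-thickness midline strip. Facet groups:
#' `"inner_surface"` (concave side), `"outer_surface"`, and
#' `"trephine_wall"` when a hole exists. Node group `"fixed_edges"` holds
#' all four lateral boundary edges through the thickness. Loops
#' `"trephine_inner_loop"` / `"trephine_outer_loop"` are the hole rims on
#' the innermost and outermost surfaces, ordered counter-clockwise.
#'
#' @param spec a [phantom_spec()].
#' @return A [tet_mesh()].
#' @export
build_wall_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  pm <- wall_plane_mesh(spec)
  # sheet offsets, inner (TR) at the bottom
  t_oi <- spec$layer_thicknesses            # outer -> inner: EO IO RA TR
  t_io <- rev(t_oi)                         # inner -> outer
  zsheet <- cumsum(c(0, t_io)) - sum(t_io) / 2
  ex <- extrude_triangulation(pm$points, pm$tris, zsheet)
  prisms <- ex$prisms
  tets <- prisms_to_tets(prisms)
  layer_tag_io <- c("TR", "RA", "IO", "EO")
  regions3 <- rep(layer_tag_io[ex$layer], 3L)   # tets i, n+i, 2n+i per prism

  nodes <- ex$nodes                             # parametric (x, y, z)
  n2 <- nrow(pm$points)

  # stiff midline strip: full thickness. Membership is decided per parent
  # quad (not per tet) so the tag field is exactly mirror-symmetric.
  ntri <- nrow(pm$tris)
  tet_tri <- rep(rep(seq_len(ntri), length(zsheet) - 1L), 3L)
  regions3[abs(pm$tri_quad_cx)[tet_tri] < spec$strip_width / 2] <- "LA"

  # optional deterministic jitter of interior in-plane nodes
  if (spec$seed > 0L) {
    nodes <- jitter_wall_nodes(nodes, pm, spec)
  }

  groups <- wall_groups(nodes, tets, pm, spec, zsheet, n2)

  # bend to the cylinder: per-sheet isometric development
  if (is.finite(spec$curvature_radius)) {
    Rc <- spec$curvature_radius
    rho <- Rc + nodes[, 3]
    th <- nodes[, 1] / rho
    nodes <- cbind(rho * sin(th), nodes[, 2], rho * cos(th) - Rc)
  }

  tet_mesh(nodes, tets, regions3,
           facet_groups = groups$facet_groups,
           node_groups = groups$node_groups,
           loops = groups$loops,
           repair = FALSE)
}

jitter_wall_nodes <- function(nodes, pm, spec) {
  set.seed(spec$seed)
  W <- spec$width; H <- spec$height
  movable <- abs(nodes[, 1]) < W / 2 - 1e-9 & nodes[, 2] > 1e-9 &
             nodes[, 2] < H - 1e-9 &
             abs(abs(nodes[, 1]) - spec$strip_width / 2) > 1e-9
  if (!is.null(pm$circle)) {
    ctr <- stoma_positions(spec)
    ctr <- ctr[ctr$label == spec$hole_position, ]
    d <- sqrt((nodes[, 1] - ctr$x)^2 + (nodes[, 2] - ctr$y)^2)
    movable <- movable & d > spec$hole_diameter   # leave the O-grid alone
  }
  amp <- 0.05 * spec$resolution
  nodes[movable, 1] <- nodes[movable, 1] + stats::runif(sum(movable), -amp, amp)
  nodes[movable, 2] <- nodes[movable, 2] + stats::runif(sum(movable), -amp, amp)
  nodes
}

wall_groups <- function(nodes, tets, pm, spec, zsheet, n2) {
  W <- spec$width; H <- spec$height
  zin <- zsheet[1L]; zout <- zsheet[length(zsheet)]
  bf <- mesh_boundary_faces_raw(nodes, tets)
  fz <- cbind(nodes[bf[, 1], 3], nodes[bf[, 2], 3], nodes[bf[, 3], 3])
  on_in <- rowSums(abs(fz - zin) < 1e-9) == 3L
  on_out <- rowSums(abs(fz - zout) < 1e-9) == 3L
  facet_groups <- list(inner_surface = bf[on_in, , drop = FALSE],
                       outer_surface = bf[on_out, , drop = FALSE])
  node_groups <- list(fixed_edges = which(
    abs(abs(nodes[, 1]) - W / 2) < 1e-9 |
    nodes[, 2] < 1e-9 | nodes[, 2] > H - 1e-9))
  loops <- list()
  if (!is.null(pm$circle)) {
    ctr <- stoma_positions(spec)
    ctr <- ctr[ctr$label == spec$hole_position, ]
    r <- spec$hole_diameter / 2
    d <- sqrt((nodes[, 1] - ctr$x)^2 + (nodes[, 2] - ctr$y)^2)
    on_circ <- abs(d - r) < 1e-7
    fcirc <- matrix(on_circ[bf], ncol = 3L)
    facet_groups$trephine_wall <- bf[rowSums(fcirc) == 3L, , drop = FALSE]
    nsheet <- length(zsheet)
    loops$trephine_inner_loop <- pm$circle
    loops$trephine_outer_loop <- pm$circle + (nsheet - 1L) * n2
  }
  list(facet_groups = facet_groups, node_groups = node_groups, loops = loops)
}

mesh_boundary_faces_raw <- function(nodes, tets) {
  faces <- all_tet_faces(tets)
  key <- face_key_fast(faces)
  tab <- table(key)
  faces[key %in% names(tab)[tab == 1L], , drop = FALSE]
}
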