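#' Read a Gmsh `.msh` file into a tet_mesh
#'
#' Supports ASCII MSH version 4.1 (as produced by [write_gmsh()]) and the
#' legacy version 2.2. Physical volume groups become region tags, physical
#' surface groups (triangles) become facet groups, physical curve groups
#' (line chains) are reassembled into ordered loops, and physical point
#' groups become node groups. Only linear (4-node) tetrahedra are accepted;
#' negatively oriented tetrahedra are repaired with a message.
#'
#' @param path path to an ASCII `.msh` file.
#' @return A [tet_mesh()].
#' @export
read_gmsh <- function(path) {
  lines <- readLines(path, warn = FALSE)
  sec <- function(name) {
    i1 <- match(paste0("$", name), lines)
    i2 <- match(paste0("$End", name), lines)
    if (is.na(i1) || is.na(i2)) return(NULL)
    lines[(i1 + 1L):(i2 - 1L)]
  }
  fmt <- sec("MeshFormat")
  if (is.null(fmt)) stop("unsupported msh dialect: missing $MeshFormat")
  ver <- strsplit(trimws(fmt[1L]), "\\s+")[[1L]]
  if (ver[2L] != "0") stop("unsupported msh dialect: binary msh not supported")
  version <- as.numeric(ver[1L])
  if (version >= 4 && version < 5) {
    parse_msh4(sec)
  } else if (abs(version - 2.2) < 1e-9) {
    parse_msh2(sec)
  } else {
    stop("unsupported msh dialect: version ", ver[1L])
  }
}

parse_physical_names <- function(txt) {
  if (is.null(txt)) {
    return(tibble::tibble(dim = integer(), tag = integer(), name = character()))
  }
  n <- as.integer(txt[1L])
  rows <- txt[seq_len(n) + 1L]
  m <- regmatches(rows, regexec('^\\s*(\\d+)\\s+(\\d+)\\s+"(.*)"\\s*$', rows))
  tibble::tibble(dim = as.integer(vapply(m, `[`, "", 2L)),
                 tag = as.integer(vapply(m, `[`, "", 3L)),
                 name = vapply(m, `[`, "", 4L))
}

scan_tokens <- function(txt) {
  as.numeric(unlist(strsplit(trimws(txt[nzchar(trimws(txt))]), "\\s+"),
                    use.names = FALSE))
}

parse_msh4 <- function(sec) {
  phys <- parse_physical_names(sec("PhysicalNames"))
  # Entities: map (dim, entityTag) -> first physical tag
  ent <- scan_tokens(sec("Entities"))
  np <- ent[1L]; nc <- ent[2L]; ns <- ent[3L]; nv <- ent[4L]
  pos <- 5L
  ent_phys <- list()
  read_entity <- function(dim, has_bbox) {
    tag <- ent[pos]
    pos <<- pos + 1L + (if (has_bbox) 6L else 3L)
    nph <- ent[pos]; pos <<- pos + 1L
    ph <- if (nph > 0) ent[pos:(pos + nph - 1L)] else numeric(0)
    pos <<- pos + nph
    if (dim > 0L) {
      nb <- ent[pos]; pos <<- pos + 1L + nb
    }
    ent_phys[[paste(dim, tag)]] <<- as.integer(ph)
  }
  for (i in seq_len(np)) read_entity(0L, FALSE)
  for (i in seq_len(nc)) read_entity(1L, TRUE)
  for (i in seq_len(ns)) read_entity(2L, TRUE)
  for (i in seq_len(nv)) read_entity(3L, TRUE)

  nod <- scan_tokens(sec("Nodes"))
  nblocks <- nod[1L]; nnodes <- nod[2L]
  pos <- 5L
  tags <- integer(nnodes); coords <- matrix(0, nnodes, 3L)
  got <- 0L
  for (b in seq_len(nblocks)) {
    nb <- nod[pos + 3L]
    if (nb > 0) {
      idx <- got + seq_len(nb)
      tags[idx] <- as.integer(nod[pos + 4L - 1L + seq_len(nb)])
      cc <- nod[pos + 3L + nb + seq_len(3L * nb)]
      coords[idx, ] <- matrix(cc, nb, 3L, byrow = TRUE)
      got <- got + nb
    }
    pos <- pos + 4L + 4L * nb
  }
  node_of_tag <- integer(max(tags))
  node_of_tag[tags] <- seq_along(tags)

  ele <- scan_tokens(sec("Elements"))
  nblocks <- ele[1L]
  pos <- 5L
  elems <- list()
  for (b in seq_len(nblocks)) {
    dim <- as.integer(ele[pos]); etag <- as.integer(ele[pos + 1L])
    type <- as.integer(ele[pos + 2L]); nb <- ele[pos + 3L]
    pos <- pos + 4L
    npe <- switch(as.character(type), "15" = 1L, "1" = 2L, "2" = 3L, "4" = 4L,
                  NA_integer_)
    if (is.na(npe)) stop("unsupported msh dialect: element type ", type,
                         " (only linear points/lines/triangles/tetrahedra)")
    block <- matrix(ele[pos - 1L + seq_len((npe + 1L) * nb)], nb, npe + 1L,
                    byrow = TRUE)
    pos <- pos + (npe + 1L) * nb
    elems[[length(elems) + 1L]] <- list(
      dim = dim, phys = ent_phys[[paste(dim, etag)]], type = type,
      nodes = matrix(node_of_tag[as.integer(block[, -1L, drop = FALSE])],
                     nb, npe))
  }
  assemble_mesh_from_blocks(coords, elems, phys)
}

parse_msh2 <- function(sec) {
  phys <- parse_physical_names(sec("PhysicalNames"))
  nod <- scan_tokens(sec("Nodes"))
  nnodes <- as.integer(nod[1L])
  body <- matrix(nod[-1L], nnodes, 4L, byrow = TRUE)
  tags <- as.integer(body[, 1L])
  coords <- body[, 2:4, drop = FALSE]
  node_of_tag <- integer(max(tags))
  node_of_tag[tags] <- seq_along(tags)

  etxt <- sec("Elements")
  ne <- as.integer(etxt[1L])
  elems <- list()
  for (r in seq_len(ne)) {
    v <- as.numeric(strsplit(trimws(etxt[r + 1L]), "\\s+")[[1L]])
    type <- as.integer(v[2L]); ntags <- as.integer(v[3L])
    ph <- if (ntags >= 1L) as.integer(v[4L]) else integer(0)
    nds <- as.integer(v[(4L + ntags):length(v)])
    npe <- switch(as.character(type), "15" = 1L, "1" = 2L, "2" = 3L, "4" = 4L,
                  NA_integer_)
    if (is.na(npe)) stop("unsupported msh dialect: element type ", type)
    dim <- c("15" = 0L, "1" = 1L, "2" = 2L, "4" = 3L)[[as.character(type)]]
    elems[[r]] <- list(dim = dim, phys = ph, type = type,
                       nodes = matrix(node_of_tag[nds], 1L, npe))
  }
  assemble_mesh_from_blocks(coords, elems, phys)
}

assemble_mesh_from_blocks <- function(coords, elems, phys) {
  phys_name <- function(dim, tag) {
    hit <- phys$name[phys$dim == dim & phys$tag %in% tag]
    if (length(hit)) hit[1L] else if (length(tag)) paste0("group_", tag[1L])
    else NA_character_
  }
  tets <- list(); regions <- list()
  tris <- list(); tri_group <- list()
  segs <- list(); seg_group <- list()
  pnts <- list(); pnt_group <- list()
  for (e in elems) {
    if (e$type == 4L) {
      nm <- phys_name(3L, e$phys)
      if (is.na(nm)) stop("untagged region")
      tets[[length(tets) + 1L]] <- e$nodes
      regions[[length(regions) + 1L]] <- rep(nm, nrow(e$nodes))
    } else if (e$type == 2L) {
      nm <- phys_name(2L, e$phys)
      if (!is.na(nm)) {
        tris[[length(tris) + 1L]] <- e$nodes
        tri_group[[length(tri_group) + 1L]] <- rep(nm, nrow(e$nodes))
      }
    } else if (e$type == 1L) {
      nm <- phys_name(1L, e$phys)
      if (!is.na(nm)) {
        segs[[length(segs) + 1L]] <- e$nodes
        seg_group[[length(seg_group) + 1L]] <- rep(nm, nrow(e$nodes))
      }
    } else if (e$type == 15L) {
      nm <- phys_name(0L, e$phys)
      if (!is.na(nm)) {
        pnts[[length(pnts) + 1L]] <- e$nodes[, 1L]
        pnt_group[[length(pnt_group) + 1L]] <- rep(nm, nrow(e$nodes))
      }
    }
  }
  if (!length(tets)) stop("no volume elements")
  tets <- do.call(rbind, tets)
  regions <- unlist(regions)

  facet_groups <- list()
  if (length(tris)) {
    tris <- do.call(rbind, tris); tg <- unlist(tri_group)
    facet_groups <- lapply(split(seq_along(tg), tg),
                           function(i) tris[i, , drop = FALSE])
  }
  node_groups <- list()
  if (length(pnts)) {
    pv <- unlist(pnts); pg <- unlist(pnt_group)
    node_groups <- lapply(split(pv, pg), function(v) sort(unique(v)))
  }
  loops <- list()
  if (length(segs)) {
    segs <- do.call(rbind, segs); sg <- unlist(seg_group)
    loops <- lapply(split(seq_along(sg), sg),
                    function(i) chain_loop(segs[i, , drop = FALSE]))
  }
  tet_mesh(coords, tets, regions, facet_groups = facet_groups,
           node_groups = node_groups, loops = loops, repair = TRUE)
}

# reassemble an ordered closed cycle from unordered line segments
chain_loop <- function(segs) {
  nxt <- segs[, 2L]
  names(nxt) <- as.character(segs[, 1L])
  start <- segs[1L, 1L]
  out <- integer(nrow(segs))
  cur <- start
  for (k in seq_len(nrow(segs))) {
    out[k] <- cur
    nx <- nxt[as.character(cur)]
    if (is.na(nx)) stop("loop physical group is not a closed chain")
    cur <- unname(nx)
  }
  if (cur != start) stop("loop physical group is not a closed chain")
  out
}

#' Write a tet_mesh as Gmsh `.msh` ASCII 4.1
#'
#' Emits the mesh with one discrete volume entity + physical group per
#' region tag, one surface entity per facet group, one curve entity (line
#' chain) per loop, and one point entity per node group, so that
#' [read_gmsh()] round-trips coordinates, connectivity and all group names.
#' Empty facet groups are omitted with a warning. An invalid mesh
#' (see [validate_mesh()]) is refused.
#'
#' @param mesh a [tet_mesh()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gmsh <- function(mesh, path) {
  rep_ <- validate_mesh(mesh)
  if (nrow(rep_) > 0L) {
    stop("refusing to write invalid mesh: ", rep_$component[1L], ": ",
         rep_$problem[1L], if (nrow(rep_) > 1L)
           paste0(" (and ", nrow(rep_) - 1L, " more problems)") else "")
  }
  empty <- names(mesh$facet_groups)[vapply(mesh$facet_groups, nrow, 1L) == 0L]
  if (length(empty)) {
    warning("omitting empty facet group(s): ", paste(empty, collapse = ", "))
  }
  fgroups <- mesh$facet_groups[vapply(mesh$facet_groups, nrow, 1L) > 0L]
  ngroups <- mesh$node_groups[lengths(mesh$node_groups) > 0L]
  loops <- mesh$loops[lengths(mesh$loops) > 0L]
  rtags <- sort(unique(mesh$regions))

  # physical tags: one shared counter across dimensions
  ptag <- 0L
  phys <- list()
  add_phys <- function(dim, name) {
    ptag <<- ptag + 1L
    phys[[length(phys) + 1L]] <<- sprintf('%d %d "%s"', dim, ptag, name)
    ptag
  }
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(c(...), con)
  w("$MeshFormat", "4.1 0 8", "$EndMeshFormat")

  pt_node <- lapply(ngroups, identity)
  tag_pts <- integer(length(ngroups))
  tag_crv <- integer(length(loops))
  tag_srf <- integer(length(fgroups))
  tag_vol <- integer(length(rtags))
  for (i in seq_along(ngroups)) tag_pts[i] <- add_phys(0L, names(ngroups)[i])
  for (i in seq_along(loops)) tag_crv[i] <- add_phys(1L, names(loops)[i])
  for (i in seq_along(fgroups)) tag_srf[i] <- add_phys(2L, names(fgroups)[i])
  for (i in seq_along(rtags)) tag_vol[i] <- add_phys(3L, rtags[i])
  w("$PhysicalNames", as.character(length(phys)), unlist(phys),
    "$EndPhysicalNames")

  bb <- c(apply(mesh$nodes, 2L, min), apply(mesh$nodes, 2L, max))
  bbs <- paste(sprintf("%.12g", bb), collapse = " ")
  # one point entity per node group, one curve per loop, one surface per
  # facet group, one volume per region; no bounding entities
  w("$Entities", paste(length(ngroups), length(loops), length(fgroups),
                       length(rtags)))
  for (i in seq_along(ngroups)) {
    p <- mesh$nodes[ngroups[[i]][1L], ]
    w(sprintf("%d %.12g %.12g %.12g 1 %d", i, p[1], p[2], p[3], tag_pts[i]))
  }
  for (i in seq_along(loops)) w(sprintf("%d %s 1 %d 0", i, bbs, tag_crv[i]))
  for (i in seq_along(fgroups)) w(sprintf("%d %s 1 %d 0", i, bbs, tag_srf[i]))
  for (i in seq_along(rtags)) w(sprintf("%d %s 1 %d 0", i, bbs, tag_vol[i]))
  w("$EndEntities")

  n <- nrow(mesh$nodes)
  w("$Nodes", sprintf("1 %d 1 %d", n, n),
    sprintf("3 1 0 %d", n),
    as.character(seq_len(n)),
    sprintf("%.17g %.17g %.17g", mesh$nodes[, 1], mesh$nodes[, 2],
            mesh$nodes[, 3]),
    "$EndNodes")

  blocks <- character(0)
  etag <- 0L
  nelem_total <- 0L
  add_block <- function(dim, enttag, type, conn) {
    nb <- nrow(conn)
    ids <- etag + seq_len(nb)
    etag <<- etag + nb
    nelem_total <<- nelem_total + nb
    c(sprintf("%d %d %d %d", dim, enttag, type, nb),
      paste(ids, apply(conn, 1L, paste, collapse = " ")))
  }
  for (i in seq_along(ngroups)) {
    blocks <- c(blocks, add_block(0L, i, 15L, matrix(ngroups[[i]], ncol = 1L)))
  }
  for (i in seq_along(loops)) {
    l <- loops[[i]]
    blocks <- c(blocks, add_block(1L, i, 1L, cbind(l, c(l[-1L], l[1L]))))
  }
  for (i in seq_along(fgroups)) {
    blocks <- c(blocks, add_block(2L, i, 2L, fgroups[[i]]))
  }
  for (i in seq_along(rtags)) {
    conn <- mesh$tets[mesh$regions == rtags[i], , drop = FALSE]
    blocks <- c(blocks, add_block(3L, i, 4L, conn))
  }
  nb <- length(ngroups) + length(loops) + length(fgroups) + length(rtags)
  w("$Elements", sprintf("%d %d 1 %d", nb, nelem_total, nelem_total), blocks,
    "$EndElements")
  invisible(path)
}
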