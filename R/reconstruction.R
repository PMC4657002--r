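# ---------------------------------------------------------------------------
# 3D reconstruction: link typed contours across the registered stack into
# lineage tracks (tolerating splits and merges), loft each constant-type
# track segment into a triangulated tube, and export coloured PLY/OBJ
# surfaces plus an optional per-section voxel labelmap.
#
# Geometry conventions: mesh x = col (px), y = row (px), z = section index
# times the slice spacing (mm).  Type colours follow the histology
# convention: yellow = sensory, green = motor, purple = mixed.
# ---------------------------------------------------------------------------

TYPE_COLORS <- list(sensory = c(255L, 215L, 0L),
                    motor = c(0L, 160L, 0L),
                    mixed = c(160L, 32L, 240L),
                    unknown = c(128L, 128L, 128L))

polygon_jaccard <- function(poly_a, poly_b, image_size) {
  ma <- which(rasterize_polygon(poly_a, image_size[1], image_size[2]))
  mb <- which(rasterize_polygon(poly_b, image_size[1], image_size[2]))
  inter <- length(intersect(ma, mb))
  uni <- length(ma) + length(mb) - inter
  if (uni == 0) return(0)
  inter / uni
}

#' Link contours of consecutive sections into a lineage graph
#'
#' Contours of section s and s+1 are linked when their rasterized Jaccard
#' overlap reaches `jaccard_min`; ambiguous many-to-many overlaps are
#' resolved greedily by descending Jaccard with at most two children per
#' parent and two parents per child.  One-to-two link patterns are splits,
#' two-to-one merges.
#'
#' @param contour_sections list (per section) of lists of closed polygons in
#'   the common registered frame.
#' @param image_size (rows, cols) of the registered frame.
#' @param jaccard_min link threshold (default 0.2; an area-preserving
#'   two-into-one merge caps the parent-child overlap near 0.35, so 0.3
#'   leaves no margin for contour wobble, while non-corresponding fascicles
#'   sit at 0).
#' @param types optional list (parallel to `contour_sections`) of type labels.
#' @return `contour_linkage`: list with `links` (data.frame section, from,
#'   to, jaccard), `nodes`, `tracks` (constant-type chains as lists of
#'   (section, contour) indices), and `events` (split/merge records).
#' @export
link_contours <- function(contour_sections, image_size, jaccard_min = 0.2,
                          types = NULL) {
  n_sec <- length(contour_sections)
  links <- data.frame(section = integer(), from = integer(), to = integer(),
                      jaccard = numeric())
  for (s in seq_len(n_sec - 1)) {
    ca <- contour_sections[[s]]; cb <- contour_sections[[s + 1]]
    if (length(ca) == 0 || length(cb) == 0) next
    cand <- expand.grid(from = seq_along(ca), to = seq_along(cb))
    cand$jaccard <- mapply(function(i, j)
      polygon_jaccard(ca[[i]], cb[[j]], image_size), cand$from, cand$to)
    cand <- cand[cand$jaccard >= jaccard_min, , drop = FALSE]
    cand <- cand[order(-cand$jaccard), , drop = FALSE]
    out_deg <- integer(length(ca)); in_deg <- integer(length(cb))
    for (q in seq_len(nrow(cand))) {
      i <- cand$from[q]; j <- cand$to[q]
      if (out_deg[i] >= 2 || in_deg[j] >= 2) next
      # a contour may fan out (split) or fan in (merge) but not both sides
      links <- rbind(links, data.frame(section = s - 1L, from = i, to = j,
                                       jaccard = cand$jaccard[q]))
      out_deg[i] <- out_deg[i] + 1L
      in_deg[j] <- in_deg[j] + 1L
    }
  }

  node_id <- function(s, i) sprintf("s%d_c%d", s, i)
  nodes <- do.call(rbind, lapply(seq_len(n_sec), function(s) {
    k <- length(contour_sections[[s]])
    if (k == 0) return(NULL)
    data.frame(id = vapply(seq_len(k), function(i) node_id(s - 1L, i), ""),
               section = s - 1L, contour = seq_len(k),
               type = if (is.null(types)) NA_character_ else
                 types[[s]][seq_len(k)])
  }))

  # degree bookkeeping per node
  key <- function(s, i) paste(s, i)
  outdeg <- table(key(links$section, links$from))
  indeg <- table(key(links$section + 1L, links$to))
  get_deg <- function(tab, k) if (k %in% names(tab)) as.integer(tab[[k]]) else 0L

  events <- data.frame(section = integer(), event = character())
  for (k in names(outdeg)[outdeg == 2])
    events <- rbind(events, data.frame(
      section = as.integer(strsplit(k, " ")[[1]][1]) + 1L, event = "split"))
  for (k in names(indeg)[indeg == 2])
    events <- rbind(events, data.frame(
      section = as.integer(strsplit(k, " ")[[1]][1]), event = "merge"))

  # tracks: maximal chains of 1-1 links with constant type
  type_of <- function(s, i) {
    if (is.null(types)) NA_character_ else types[[s + 1L]][i]
  }
  succ <- function(s, i) {
    rows <- links[links$section == s & links$from == i, , drop = FALSE]
    if (nrow(rows) != 1) return(NULL)          # split or track end
    if (get_deg(indeg, key(s + 1L, rows$to)) != 1) return(NULL)  # merge ahead
    c(rows$to)
  }
  visited <- character(0)
  tracks <- list()
  for (row in seq_len(nrow(nodes))) {
    s <- nodes$section[row]; i <- nodes$contour[row]
    id <- node_id(s, i)
    if (id %in% visited) next
    # start a chain only at nodes with no unique same-type predecessor chain
    prev_rows <- links[links$section == s - 1L & links$to == i, , drop = FALSE]
    starts <- nrow(prev_rows) != 1 ||
      get_deg(outdeg, key(s - 1L, prev_rows$from[1])) != 1 ||
      (!is.null(types) &&
         !identical(type_of(s - 1L, prev_rows$from[1]), type_of(s, i)))
    if (!starts) next
    chain_s <- s; chain_i <- i
    sec_list <- s; con_list <- i
    visited <- c(visited, id)
    repeat {
      nx <- succ(chain_s, chain_i)
      if (is.null(nx)) break
      if (!is.null(types) &&
          !identical(type_of(chain_s, chain_i), type_of(chain_s + 1L, nx)))
        break
      chain_s <- chain_s + 1L; chain_i <- nx
      sec_list <- c(sec_list, chain_s); con_list <- c(con_list, chain_i)
      visited <- c(visited, node_id(chain_s, chain_i))
    }
    tracks[[length(tracks) + 1]] <- list(
      sections = sec_list, contours = con_list,
      type = type_of(sec_list[1], con_list[1]))
  }

  structure(list(links = links, nodes = nodes, tracks = tracks,
                 events = events, image_size = image_size),
            class = "contour_linkage")
}

# orient a polygon counter-clockwise in (x = col, y = -row) convention
orient_ccw <- function(poly) {
  n <- nrow(poly)
  x <- poly[, 2]; y <- -poly[, 1]
  a <- sum(x * y[c(2:n, 1)] - x[c(2:n, 1)] * y)
  if (a < 0) poly[n:1, , drop = FALSE] else poly
}

best_cyclic_shift <- function(ra, rb) {
  n <- nrow(ra)
  costs <- vapply(0:(n - 1), function(s) {
    idx <- ((seq_len(n) - 1 + s) %% n) + 1
    sum((ra - rb[idx, ])^2)
  }, numeric(1))
  s <- which.min(costs) - 1
  idx <- ((seq_len(n) - 1 + s) %% n) + 1
  rb[idx, , drop = FALSE]
}

#' Loft linked contour tracks into triangulated tube meshes
#'
#' Every constant-type track segment becomes one open-ended tube: its
#' contours are resampled to `n_ring` vertices, oriented consistently,
#' rotationally aligned (cyclic shift minimizing summed vertex distance) and
#' joined ring-to-ring with shortest-diagonal triangles.  At a split the
#' parent's last ring is prepended to each child segment, at a merge the
#' child's first ring is appended to each parent segment, so the junction is
#' stitched by the ordinary lofting step.
#'
#' @param linkage `contour_linkage` from [link_contours()].
#' @param contour_sections the polygon lists used to build the linkage.
#' @param z_spacing_mm section spacing (default 0.5 mm).
#' @param n_ring vertices per ring.
#' @return list of `fascicle_mesh` objects: `vertices` (x, y in px, z in mm),
#'   `faces` (1-based triangles), `color`, `type`, `sections`.
#' @export
build_meshes <- function(linkage, contour_sections, z_spacing_mm = 0.5,
                         n_ring = 100L) {
  meshes <- list()
  links <- linkage$links
  for (tr in linkage$tracks) {
    secs <- tr$sections; cons <- tr$contours
    rings <- list(); zs <- numeric(0)
    # prepend the parent's last ring when this segment starts at a split/merge child
    first_s <- secs[1]; first_i <- cons[1]
    prev <- links[links$section == first_s - 1L & links$to == first_i, ,
                  drop = FALSE]
    if (nrow(prev) == 1) {   # unique parent (split child): stitch to parent
      rings[[1]] <- contour_sections[[first_s]][[prev$from[1]]]
      zs <- (first_s - 1L) * z_spacing_mm
    }
    for (q in seq_along(secs)) {
      rings[[length(rings) + 1]] <- contour_sections[[secs[q] + 1L]][[cons[q]]]
      zs <- c(zs, secs[q] * z_spacing_mm)
    }
    last_s <- secs[length(secs)]; last_i <- cons[length(cons)]
    nxt <- links[links$section == last_s & links$from == last_i, ,
                 drop = FALSE]
    if (nrow(nxt) == 1) {    # unique child (merge parent): stitch to child
      rings[[length(rings) + 1]] <- contour_sections[[last_s + 2L]][[nxt$to[1]]]
      zs <- c(zs, (last_s + 1L) * z_spacing_mm)
    }
    if (length(rings) < 2) {
      warning("track of a single section: degenerate mesh skipped")
      next
    }
    rings <- lapply(rings, function(p) resample_closed(orient_ccw(p), n_ring))
    for (q in seq(2, length(rings)))
      rings[[q]] <- best_cyclic_shift(rings[[q - 1]], rings[[q]])

    nr <- length(rings)
    verts <- do.call(rbind, lapply(seq_len(nr), function(q)
      cbind(x = rings[[q]][, 2], y = rings[[q]][, 1], z = zs[q])))
    faces <- matrix(0L, 0, 3)
    for (q in seq_len(nr - 1)) {
      o1 <- (q - 1L) * n_ring; o2 <- q * n_ring
      r1 <- rings[[q]]; r2 <- rings[[q + 1]]
      for (i in seq_len(n_ring)) {
        j <- i %% n_ring + 1L
        d1 <- sum((r1[i, ] - r2[j, ])^2)
        d2 <- sum((r1[j, ] - r2[i, ])^2)
        if (d1 <= d2) {
          faces <- rbind(faces, c(o1 + i, o2 + i, o2 + j),
                         c(o1 + i, o2 + j, o1 + j))
        } else {
          faces <- rbind(faces, c(o1 + i, o2 + i, o1 + j),
                         c(o1 + j, o2 + i, o2 + j))
        }
      }
    }
    type <- if (is.na(tr$type) || is.null(tr$type)) "unknown" else tr$type
    meshes[[length(meshes) + 1]] <- structure(list(
      vertices = verts, faces = faces,
      color = TYPE_COLORS[[type]], type = type, sections = secs),
      class = "fascicle_mesh")
  }
  meshes
}

#' Total surface area of a triangulated mesh
#' @param mesh `fascicle_mesh`.
#' @return scalar area (in the mesh's mixed px/mm units).
#' @export
mesh_surface_area <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 2], ] - v[f[, 1], ]
  b <- v[f[, 3], ] - v[f[, 1], ]
  cr <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
              a[, 3] * b[, 1] - a[, 1] * b[, 3],
              a[, 1] * b[, 2] - a[, 2] * b[, 1])
  sum(sqrt(rowSums(cr^2))) / 2
}

#' Euler characteristic V - E + F of a mesh
#' @param mesh `fascicle_mesh`.
#' @return integer; 0 for an open-ended tube.
#' @export
mesh_euler_characteristic <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  e <- unique(t(apply(e, 1, sort)))
  nrow(mesh$vertices) - nrow(e) + nrow(f)
}

#' Export meshes as PLY and/or OBJ, with an optional voxel labelmap
#'
#' PLY files are ASCII with per-face uchar colours; OBJ output writes a
#' companion .mtl with one material per fascicle type.  The labelmap (one
#' ASCII PGM page per section, pixel value = contour index) round-trips the
#' rasterized input contours exactly.
#'
#' @param meshes list of `fascicle_mesh`.
#' @param out_path output file path (extension replaced as needed).
#' @param format `"ply"` or `"obj"`.
#' @param labelmap optional list: `contour_sections`, `image_size`, `dir`.
#' @return invisible character vector of files written.
#' @export
export_model <- function(meshes, out_path, format = "ply", labelmap = NULL) {
  supported <- c("ply", "obj")
  if (!format %in% supported)
    abort("fascicle3d_format_error",
          sprintf("unsupported format '%s'; supported: %s", format,
                  paste(supported, collapse = ", ")))
  files <- switch(format,
                  ply = write_ply(meshes, out_path),
                  obj = write_obj(meshes, out_path))
  if (!is.null(labelmap)) {
    files <- c(files, export_labelmap(labelmap$contour_sections,
                                      labelmap$image_size, labelmap$dir))
  }
  invisible(files)
}

#' Write meshes into one ASCII PLY file with per-face colours
#' @param meshes list of `fascicle_mesh`; `path` output file.
#' @return the path, invisibly.
#' @export
write_ply <- function(meshes, path) {
  nv <- sum(vapply(meshes, function(m) nrow(m$vertices), integer(1)))
  nf <- sum(vapply(meshes, function(m) nrow(m$faces), integer(1)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               "comment fascicle3d surface model; x,y px; z mm",
               sprintf("element vertex %d", nv),
               "property float x", "property float y", "property float z",
               sprintf("element face %d", nf),
               "property list uchar int vertex_indices",
               "property uchar red", "property uchar green",
               "property uchar blue", "end_header"), con)
  for (m in meshes)
    writeLines(sprintf("%.4f %.4f %.4f", m$vertices[, 1], m$vertices[, 2],
                       m$vertices[, 3]), con)
  off <- 0L
  for (m in meshes) {
    f0 <- m$faces - 1L + off
    writeLines(sprintf("3 %d %d %d %d %d %d", f0[, 1], f0[, 2], f0[, 3],
                       m$color[1], m$color[2], m$color[3]), con)
    off <- off + nrow(m$vertices)
  }
  invisible(path)
}

#' Minimal reader for PLY files written by [write_ply()]
#' @param path ASCII PLY file.
#' @return list with `vertices`, `faces` (1-based) and `face_colors`.
#' @export
read_ply <- function(path) {
  lines <- readLines(path)
  endh <- which(lines == "end_header")
  nv <- as.integer(sub("element vertex ", "",
                       grep("^element vertex", lines, value = TRUE)))
  nf <- as.integer(sub("element face ", "",
                       grep("^element face", lines, value = TRUE)))
  vl <- lines[(endh + 1):(endh + nv)]
  verts <- do.call(rbind, lapply(strsplit(vl, " "), as.numeric))
  fl <- lines[(endh + nv + 1):(endh + nv + nf)]
  fm <- do.call(rbind, lapply(strsplit(fl, " "), as.numeric))
  list(vertices = verts, faces = fm[, 2:4, drop = FALSE] + 1,
       face_colors = fm[, 5:7, drop = FALSE])
}

#' Write meshes as OBJ + MTL with one material per type
#' @param meshes list of `fascicle_mesh`; `path` output .obj path.
#' @return character vector: obj and mtl paths, invisibly.
#' @export
write_obj <- function(meshes, path) {
  mtl_path <- sub("\\.obj$", ".mtl", path)
  if (mtl_path == path) mtl_path <- paste0(path, ".mtl")
  types <- unique(vapply(meshes, function(m) m$type, character(1)))
  mtl <- c()
  for (ty in types) {
    col <- TYPE_COLORS[[ty]] / 255
    mtl <- c(mtl, sprintf("newmtl %s", ty),
             sprintf("Kd %.3f %.3f %.3f", col[1], col[2], col[3]), "")
  }
  writeLines(mtl, mtl_path)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("mtllib %s", basename(mtl_path)), con)
  off <- 0L
  for (i in seq_along(meshes)) {
    m <- meshes[[i]]
    writeLines(sprintf("o fascicle_%d", i), con)
    writeLines(sprintf("usemtl %s", m$type), con)
    writeLines(sprintf("v %.4f %.4f %.4f", m$vertices[, 1], m$vertices[, 2],
                       m$vertices[, 3]), con)
    f <- m$faces + off
    writeLines(sprintf("f %d %d %d", f[, 1], f[, 2], f[, 3]), con)
    off <- off + nrow(m$vertices)
  }
  invisible(c(path, mtl_path))
}

#' Export a per-section voxel labelmap (ASCII PGM pages)
#'
#' Page k holds the rasterization of section k's contours, pixel value =
#' contour index (0 background, later contours win ties).
#'
#' @param contour_sections list (per section) of polygon lists.
#' @param image_size (rows, cols).
#' @param dir output directory.
#' @return character vector of page paths, invisibly.
#' @export
export_labelmap <- function(contour_sections, image_size, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(length(contour_sections))
  for (s in seq_along(contour_sections)) {
    page <- matrix(0L, image_size[1], image_size[2])
    for (i in seq_along(contour_sections[[s]])) {
      poly <- contour_sections[[s]][[i]]
      if (is.null(poly)) next
      page[rasterize_polygon(poly, image_size[1], image_size[2])] <- i
    }
    paths[s] <- file.path(dir, sprintf("labelmap_%03d.pgm", s - 1L))
    write_pnm(page, paths[s])
  }
  invisible(paths)
}
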