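# ---------------------------------------------------------------------------
# Fascicle segmentation.
#
# A section's fascicles are granular dark-pixel regions broken by voids, so
# plain edge detection or region growing fails on them.  Instead:
#   1. preprocessing turns the granular texture into solid foreground
#      components (blur -> Otsu -> size filters, landmark dots removed);
#   2. ISODATA-style dynamic clustering finds how many fascicles there are
#      and where, without knowing the count beforehand;
#   3. a GVF (gradient vector flow) active contour envelops each cluster,
#      applying -- in "improved" mode -- only the normal component of the
#      external force, since the tangential part is negligible at
#      convergence.
# ---------------------------------------------------------------------------

#' Extract the fascicle-texture foreground of a registered section
#'
#' Grayscale -> Gaussian smoothing -> Otsu threshold (dark side is
#' foreground) -> removal of components below `min_size` px -> removal of
#' landmark-dot-sized compact components.
#'
#' @param image RGB section.
#' @param blur_sigma smoothing sd in px (merges granules into solid regions).
#' @param min_size minimum surviving component area (px).
#' @param landmark_area component-area window treated as a position-line dot
#'   when the component is also compact (bounding box <= 22 px).
#' @return logical foreground matrix.
#' @export
preprocess_section <- function(image, blur_sigma = 2.5, min_size = 30,
                               landmark_area = c(80, 260)) {
  gray <- blur_gaussian(rgb_to_gray(image), blur_sigma)
  thr <- otsu_threshold(gray)
  fg <- gray < thr
  if (!any(fg))
    abort("fascicle3d_empty_section", "no foreground after thresholding")
  labels <- connected_components(fg)
  stats <- component_stats(labels)
  drop <- stats$label[stats$size < min_size |
                        (stats$size >= landmark_area[1] &
                           stats$size <= landmark_area[2] &
                           stats$height <= 22 & stats$width <= 22)]
  fg[labels %in% drop] <- FALSE
  if (!any(fg))
    abort("fascicle3d_empty_section", "no fascicle-sized foreground remains")
  fg
}

#' Foreground pixel coordinates (0-based) of a mask
#' @param mask logical matrix.
#' @return n x 2 matrix of (row, col).
#' @export
mask_points <- function(mask) {
  idx <- which(mask)
  cbind(row = (idx - 1L) %% nrow(mask), col = (idx - 1L) %/% nrow(mask))
}

principal_sd <- function(pts) {
  if (nrow(pts) < 2) return(0)
  sqrt(max(eigen(stats::cov(pts), symmetric = TRUE, only.values = FALSE)$values))
}

#' Dynamic (ISODATA-style) clustering with unknown cluster count
#'
#' Starts from a single cluster at the centroid and alternates: assign each
#' point to its nearest centre; recompute centres; split any cluster whose
#' principal-axis standard deviation exceeds `split_sigma` (new centres
#' offset along the principal axis); merge centre pairs closer than
#' `merge_dist`, closest pair first.  Fully deterministic.
#'
#' @param points n x 2 matrix of foreground pixel coordinates.
#' @param split_sigma split threshold in px (principal-axis sd).
#' @param merge_dist merge threshold in px (centre distance).
#' @param max_rounds iteration cap.
#' @return `pixel_cluster_result`: list with `k`, `centers` (k x 2, the means
#'   of their assigned pixels) and `assignment` (cluster id per point).
#' @export
cluster_fascicle_pixels <- function(points, split_sigma = 23, merge_dist = 34,
                                    max_rounds = 30L) {
  points <- rbind(points)
  stopifnot(nrow(points) >= 1)
  centers <- matrix(colMeans(points), 1, 2)
  assignment <- rep(1L, nrow(points))
  # split and merge alternate on successive rounds (classic ISODATA), with a
  # full reassignment in between -- merging immediately after a split would
  # undo it before the new centres could separate
  quiet <- 0L
  for (round in seq_len(max_rounds)) {
    d2 <- outer(rowSums(points^2), rowSums(centers^2), `+`) -
      2 * tcrossprod(points, centers)
    assignment <- max.col(-d2, ties.method = "first")
    keep <- sort(unique(assignment))
    centers <- t(vapply(keep, function(k)
      colMeans(points[assignment == k, , drop = FALSE]), numeric(2)))
    assignment <- match(assignment, keep)

    changed <- FALSE
    if (round %% 2L == 1L) {
      # split phase: fractional offset along the principal axis, so genuinely
      # bimodal clusters separate on reassignment while spurious splits fall
      # back together and re-merge
      new_centers <- list()
      for (k in seq_len(nrow(centers))) {
        pts <- points[assignment == k, , drop = FALSE]
        if (nrow(pts) >= 4) {
          eg <- eigen(stats::cov(pts), symmetric = TRUE)
          sd1 <- sqrt(max(eg$values))
          if (sd1 > split_sigma) {
            v <- eg$vectors[, which.max(eg$values)]
            new_centers[[length(new_centers) + 1]] <- centers[k, ] + 0.5 * sd1 * v
            new_centers[[length(new_centers) + 1]] <- centers[k, ] - 0.5 * sd1 * v
            changed <- TRUE
            next
          }
        }
        new_centers[[length(new_centers) + 1]] <- centers[k, ]
      }
      centers <- do.call(rbind, new_centers)
    } else {
      # merge phase: closest pair first, re-evaluate after each merge
      repeat {
        if (nrow(centers) < 2) break
        dc <- as.matrix(dist(centers))
        diag(dc) <- Inf
        mn <- which(dc == min(dc), arr.ind = TRUE)[1, ]
        if (dc[mn[1], mn[2]] >= merge_dist) break
        merged <- colMeans(centers[c(mn[1], mn[2]), , drop = FALSE])
        centers <- rbind(centers[-c(mn[1], mn[2]), , drop = FALSE], merged)
        changed <- TRUE
      }
    }
    quiet <- if (changed) 0L else quiet + 1L
    if (quiet >= 2L) break   # one full split + merge cycle without change
  }
  # final cleanup: consistent assignment (centers = mean of assigned pixels)
  # and no residual centre pair below merge_dist, whatever phase the loop
  # ended on
  repeat {
    d2 <- outer(rowSums(points^2), rowSums(centers^2), `+`) -
      2 * tcrossprod(points, centers)
    assignment <- max.col(-d2, ties.method = "first")
    keep <- sort(unique(assignment))
    centers <- t(vapply(keep, function(k)
      colMeans(points[assignment == k, , drop = FALSE]), numeric(2)))
    assignment <- match(assignment, keep)
    if (nrow(centers) < 2) break
    dc <- as.matrix(dist(centers))
    diag(dc) <- Inf
    mn <- which(dc == min(dc), arr.ind = TRUE)[1, ]
    if (dc[mn[1], mn[2]] >= merge_dist) break
    merged <- colMeans(centers[c(mn[1], mn[2]), , drop = FALSE])
    centers <- rbind(centers[-c(mn[1], mn[2]), , drop = FALSE], merged)
  }
  structure(list(k = nrow(centers), centers = centers,
                 assignment = assignment),
            class = "pixel_cluster_result")
}

#' Compute a gradient vector flow field
#'
#' Diffuses the gradient of an edge map f by iterating
#'   u <- u + dt * (mu * lap(u) - (fx^2 + fy^2) * (u - fx))
#' (and symmetrically for v with fy), extending the capture range of the
#' active contour far into homogeneous regions.
#'
#' @param edge_map edge-strength raster (typically the gradient magnitude of
#'   a smoothed grayscale).
#' @param mu regularization weight (> 0).
#' @param n_iter number of diffusion iterations.
#' @param dt time step; must satisfy the stability bound dt <= 1 / (4 mu),
#'   otherwise the configuration is rejected.
#' @return `gvf_field`: list with `u` (row component), `v` (col component),
#'   `mu`, `dt` and `iterations_run`.
#' @export
compute_gvf <- function(edge_map, mu = 0.2, n_iter = 80L, dt = 1) {
  stopifnot(mu > 0, n_iter >= 0)
  if (dt > 1 / (4 * mu) + 1e-12)
    abort("fascicle3d_config_error",
          sprintf("dt = %g violates the GVF stability bound dt <= 1/(4 mu) = %g",
                  dt, 1 / (4 * mu)))
  g <- image_gradient(edge_map)
  fx <- g$gr; fy <- g$gc
  b <- fx^2 + fy^2
  u <- fx; v <- fy
  for (i in seq_len(n_iter)) {
    u <- u + dt * (mu * laplacian(u) - b * (u - fx))
    v <- v + dt * (mu * laplacian(v) - b * (v - fy))
  }
  structure(list(u = u, v = v, mu = mu, dt = dt,
                 iterations_run = as.integer(n_iter)),
            class = "gvf_field")
}

# closed-contour helpers ------------------------------------------------------

resample_closed <- function(verts, n) {
  closed <- rbind(verts, verts[1, ])
  seg <- sqrt(rowSums(diff(closed)^2))
  cum <- c(0, cumsum(seg))
  total <- cum[length(cum)]
  if (total < 1e-9) return(matrix(rep(verts[1, ], n), n, 2, byrow = TRUE))
  s <- seq(0, total, length.out = n + 1)[1:n]
  i <- findInterval(s, cum, rightmost.closed = TRUE)
  i <- pmin(i, nrow(closed) - 1)
  f <- (s - cum[i]) / pmax(seg[i], 1e-12)
  closed[i, , drop = FALSE] * (1 - f) + closed[i + 1, , drop = FALSE] * f
}

contour_perimeter <- function(verts) {
  sum(sqrt(rowSums((verts - verts[c(2:nrow(verts), 1), ])^2)))
}

# cyclic pentadiagonal internal-energy matrix for n vertices
snake_internal_matrix <- function(n, alpha, beta, step) {
  D2 <- matrix(0, n, n)
  idx <- function(i) ((i - 1) %% n) + 1
  for (i in seq_len(n)) {
    D2[i, idx(i - 1)] <- D2[i, idx(i - 1)] + 1
    D2[i, i] <- D2[i, i] - 2
    D2[i, idx(i + 1)] <- D2[i, idx(i + 1)] + 1
  }
  D4 <- D2 %*% D2
  solve(diag(n) + step * (beta * D4 - alpha * D2))
}

sample_field <- function(field, verts) {
  cbind(bilinear_sample(field$u, verts[, 1], verts[, 2], 0),
        bilinear_sample(field$v, verts[, 1], verts[, 2], 0))
}

contour_normals <- function(verts) {
  n <- nrow(verts)
  tg <- (verts[c(2:n, 1), ] - verts[c(n, 1:(n - 1)), ]) / 2
  nv <- cbind(-tg[, 2], tg[, 1])
  len <- sqrt(rowSums(nv^2))
  nv / pmax(len, 1e-12)
}

#' Decompose the external force at the vertices of a contour
#'
#' @param verts closed contour vertices (n x 2).
#' @param field `gvf_field`.
#' @return list with mean absolute `normal` and `tangential` force
#'   components -- used to verify that the tangential part is negligible at
#'   convergence.
#' @export
snake_force_components <- function(verts, field) {
  Fv <- sample_field(field, verts)
  nrm <- contour_normals(verts)
  fn <- rowSums(Fv * nrm)
  ft <- rowSums(Fv * cbind(nrm[, 2], -nrm[, 1]))
  list(normal = mean(abs(fn)), tangential = mean(abs(ft)))
}

#' Evolve an active contour under a GVF field
#'
#' Semi-implicit update: the internal (tension alpha, rigidity beta) term is
#' handled by a pre-factored cyclic pentadiagonal system, the external GVF
#' force explicitly.  In `"improved"` mode only the component of the external
#' force along the local contour normal is applied; `"classical"` mode uses
#' the full vector.  Vertices are resampled to uniform arc length every
#' iteration; evolution stops when the maximum vertex displacement falls
#' below `tol` px or after `max_iter` iterations.
#'
#' @param init initial closed contour (m x 2, (row, col)).
#' @param field `gvf_field`.
#' @param alpha tension weight; `beta` rigidity weight; `step` time step.
#' @param max_iter iteration cap.
#' @param mode `"improved"` (normal component only) or `"classical"`.
#' @param n_vertices number of vertices maintained on the contour.
#' @param tol convergence threshold on max displacement (px).
#' @return `snake_contour`: list with `vertices`, `converged`, `iterations`
#'   and `mode`.
#' @export
evolve_snake <- function(init, field, alpha = 0.1, beta = 0.5, step = 1.0,
                         max_iter = 200L, mode = c("improved", "classical"),
                         n_vertices = 100L, tol = 0.1) {
  mode <- match.arg(mode)
  stopifnot(alpha >= 0, beta >= 0, step > 0)
  x <- resample_closed(rbind(init), n_vertices)
  Minv <- snake_internal_matrix(n_vertices, alpha, beta, step)
  iterations <- 0L
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    iterations <- it
    Fv <- sample_field(field, x)
    if (mode == "improved") {
      nrm <- contour_normals(x)
      Fv <- nrm * rowSums(Fv * nrm)
    }
    x_new <- Minv %*% (x + step * Fv)
    disp <- max(sqrt(rowSums((x_new - x)^2)))
    x <- resample_closed(x_new, n_vertices)
    if (contour_perimeter(x) < 8)
      abort("fascicle3d_collapse_error", "contour collapsed below 8 px")
    if (disp < tol) { converged <- TRUE; break }
  }
  structure(list(vertices = x, converged = converged,
                 iterations = iterations, mode = mode),
            class = "snake_contour")
}

#' Circle contour helper
#' @param center (row, col); `radius` px; `n` vertices.
#' @return n x 2 vertex matrix.
#' @export
circle_contour <- function(center, radius, n = 100L) {
  phi <- seq(0, 2 * pi, length.out = n + 1)[1:n]
  cbind(center[1] + radius * cos(phi), center[2] + radius * sin(phi))
}

# Edge map of one cluster: the smoothed grayscale inside the cluster's
# bounding box is re-thresholded locally (bimodal fascicle-vs-background, so
# the local Otsu level sits at the blur midpoint and the mask boundary at the
# true edge) and the component containing the cluster centre is kept.  The
# granule-scale raggedness of that boundary is removed by a median-like
# regularization (blur then re-threshold at 0.5, which preserves the boundary
# position), holes are filled, and the gradient magnitude of the softly
# blurred mask becomes the edge map, rescaled so that its own peak gradient
# (the GVF source strength) is 0.5 regardless of blur widths.  Raw-texture
# gradients are deliberately not used: they trap the contour in granule
# voids.
cluster_edge_map <- function(gray_blur, center, bbox, soft_sigma = 1.5,
                             reg_sigma = 2.5) {
  sub <- gray_blur[(bbox$r0:bbox$r1) + 1L, (bbox$c0:bbox$c1) + 1L]
  lab <- connected_components(sub < otsu_threshold(sub))
  kc <- lab[round(center[1]) - bbox$r0 + 1L, round(center[2]) - bbox$c0 + 1L]
  if (kc == 0) {
    st <- component_stats(lab)
    if (nrow(st) == 0) return(matrix(0, nrow(sub), ncol(sub)))
    kc <- st$label[which.max(st$size)]
  }
  mk <- lab == kc
  if (reg_sigma > 0) mk <- blur_gaussian(mk * 1, reg_sigma) >= 0.5
  soft <- blur_gaussian(fill_holes(mk) * 1, soft_sigma)
  g <- image_gradient(soft)
  em <- sqrt(g$gr^2 + g$gc^2)
  g2 <- image_gradient(em)
  mx <- max(sqrt(g2$gr^2 + g2$gc^2))
  if (mx > 0) em <- em * 0.5 / mx
  em
}

#' Extract one fascicle contour per cluster
#'
#' Each cluster's neighbourhood is re-thresholded locally and turned into a
#' solid soft mask whose gradient magnitude serves as the edge map
#' (raw-texture gradients would trap the contour inside granule voids); the
#' snake is initialized as a circle at the cluster centre with radius 1.2 x
#' the cluster RMS radius and evolved in improved mode by default.
#'
#' @param image registered RGB section (used only for its size).
#' @param clusters `pixel_cluster_result`; `points` the clustered pixel
#'   coordinates (as passed to [cluster_fascicle_pixels()]).
#' @param points n x 2 matrix matching `clusters$assignment`.
#' @param snake_params optional overrides: alpha, beta, step, max_iter, mode,
#'   n_vertices, tol, mu, gvf_iter.
#' @return list of `snake_contour` (NULL where a contour collapsed, with a
#'   warning); vertices are in full-image coordinates.
#' @export
extract_fascicle_contours <- function(image, clusters, points,
                                      snake_params = list()) {
  p <- utils::modifyList(list(alpha = 0.1, beta = 0.5, step = 1.0,
                              max_iter = 200L, mode = "improved",
                              n_vertices = 100L, tol = 0.1,
                              mu = 0.2, gvf_iter = 80L, blur_sigma = 2.5,
                              soft_sigma = 1.5, reg_sigma = 2.5),
                         snake_params)
  rows <- if (is.matrix(image)) nrow(image) else dim(image)[1]
  cols <- if (is.matrix(image)) ncol(image) else dim(image)[2]
  gray_blur <- blur_gaussian(rgb_to_gray(image), p$blur_sigma)
  out <- vector("list", clusters$k)
  for (k in seq_len(clusters$k)) {
    pts <- points[clusters$assignment == k, , drop = FALSE]
    ctr <- clusters$centers[k, ]
    rms <- sqrt(mean(rowSums(sweep(pts, 2, ctr)^2)))
    margin <- 25L
    bbox <- list(r0 = max(0L, min(pts[, 1]) - margin),
                 r1 = min(rows - 1L, max(pts[, 1]) + margin),
                 c0 = max(0L, min(pts[, 2]) - margin),
                 c1 = min(cols - 1L, max(pts[, 2]) + margin))
    em <- cluster_edge_map(gray_blur, ctr, bbox, soft_sigma = p$soft_sigma,
                           reg_sigma = p$reg_sigma)
    field <- compute_gvf(em, mu = p$mu, n_iter = p$gvf_iter)
    init <- circle_contour(ctr - c(bbox$r0, bbox$c0), 1.2 * rms,
                           p$n_vertices)
    sn <- tryCatch(
      evolve_snake(init, field, alpha = p$alpha, beta = p$beta,
                   step = p$step, max_iter = p$max_iter, mode = p$mode,
                   n_vertices = p$n_vertices, tol = p$tol),
      fascicle3d_collapse_error = function(e) {
        warning(sprintf("cluster %d: %s", k, conditionMessage(e)))
        NULL
      })
    if (!is.null(sn))
      sn$vertices <- sweep(sn$vertices, 2, c(bbox$r0, bbox$c0), `+`)
    out[[k]] <- sn
  }
  out
}
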