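# ---------------------------------------------------------------------------
# Functional typing of fascicles from neighbourhood texture.
#
# Around a pixel (m, n) a (2r+1)-wide neighbourhood is profiled along the
# four standard directions (0, 45, 90, 135 degrees).  The first-order
# gradient curve of a direction is the sequence of successive differences of
# the intensity profile (2r values, index i = m-r+1 .. m+r); the second-order
# curve is the successive differences of the first (2r-1 values).  Each curve
# is summarized by three descriptors: maximum amplitude, second-largest
# amplitude and the mean peak interval of |curve|.  With 4 + 4 curves, 3
# descriptors and 3 RGB channels this gives the fixed 72-dimensional
# per-pixel feature vector (8 x 3 x 3), whatever the value of r >= 5.
# Feature rows are clustered by rough K-means (k = 3) and clusters are named
# sensory / mixed / motor by increasing mean grayscale (sensory fascicles
# stain darkest, motor lightest).
# ---------------------------------------------------------------------------

#' Neighbourhood specification for texture descriptors
#' @param r neighbourhood scale (integer >= 5, default 11); the profiled
#'   window is 2r + 1 pixels wide.
#' @return `neighborhood_spec` with `r`, `side` and the four `directions`.
#' @export
neighborhood_spec <- function(r = 11L) {
  r <- as.integer(r)
  if (r < 5) abort("fascicle3d_config_error", "neighbourhood scale r must be >= 5")
  structure(list(r = r, side = 2L * r + 1L,
                 directions = c(0L, 45L, 90L, 135L)),
            class = "neighborhood_spec")
}

# unit steps per direction in (row, col); diagonals use nearest-neighbour
# (integer) sampling
direction_steps <- function() {
  list(`0` = c(0L, 1L), `45` = c(-1L, 1L), `90` = c(1L, 0L),
       `135` = c(1L, 1L))
}

#' Directional first- and second-order gradient curves at one pixel
#'
#' @param image RGB array (or matrix, treated as one channel).
#' @param pixel (m, n), 0-based; its full (2r+1) neighbourhood (including the
#'   diagonals) must lie inside the image, else a
#'   `fascicle3d_border_error` is raised.
#' @param spec `neighborhood_spec`.
#' @return `gradient_curves`: per channel, per direction, `first` (length 2r)
#'   and `second` (length 2r - 1) curves.
#' @export
directional_gradient_curves <- function(image, pixel, spec = neighborhood_spec()) {
  r <- spec$r
  dims <- if (is.matrix(image)) c(dim(image), 1L) else dim(image)
  m <- pixel[1]; n <- pixel[2]
  if (m < r || n < r || m > dims[1] - 1L - r || n > dims[2] - 1L - r)
    abort("fascicle3d_border_error",
          "pixel closer than r to the image border")
  steps <- direction_steps()
  ks <- (-r):r
  out <- vector("list", dims[3])
  for (ch in seq_len(dims[3])) {
    chm <- if (is.matrix(image)) image else image[, , ch]
    dir_out <- vector("list", length(steps))
    names(dir_out) <- names(steps)
    for (d in seq_along(steps)) {
      st <- steps[[d]]
      prof <- chm[cbind(m + ks * st[1] + 1L, n + ks * st[2] + 1L)]
      first <- diff(prof)
      dir_out[[d]] <- list(first = first, second = diff(first))
    }
    out[[ch]] <- dir_out
  }
  structure(list(channels = out, r = r), class = "gradient_curves")
}

#' Three descriptors of a gradient curve
#'
#' Amplitudes are the two largest values of |curve| (duplicates allowed);
#' peaks are local maxima of |curve| (strict rise, plateaus credited to
#' their leftmost index); the mean peak interval is the mean index spacing of
#' successive peaks, 0 when fewer than two peaks exist.
#'
#' @param curve numeric vector (length >= 2).
#' @return named numeric: `max_amp`, `second_max_amp`, `mean_peak_interval`.
#' @export
curve_descriptors <- function(curve) {
  a <- abs(curve)
  n <- length(a)
  s <- sort(a, decreasing = TRUE)
  peaks <- which(a[2:(n - 1)] > a[1:(n - 2)] & a[2:(n - 1)] >= a[3:n]) + 1L
  interval <- if (length(peaks) >= 2)
    (peaks[length(peaks)] - peaks[1]) / (length(peaks) - 1) else 0
  c(max_amp = s[1], second_max_amp = s[2], mean_peak_interval = interval)
}

feature_names_72 <- function() {
  as.vector(outer(
    c("max", "second", "interval"),
    as.vector(outer(c("d0", "d45", "d90", "d135"),
                    as.vector(outer(c("g1", "g2"), c("R", "G", "B"),
                                    function(o, ch) paste(ch, o, sep = "."))),
                    function(d, oc) paste(oc, d, sep = "."))),
    function(s, p) paste(p, s, sep = ".")))
}

#' Per-pixel 72-dimensional feature vector
#' @inheritParams directional_gradient_curves
#' @return named numeric vector of length 72, ordered channel (R, G, B) x
#'   curve order (first, second) x direction (0, 45, 90, 135) x descriptor
#'   (max, second, interval).
#' @export
pixel_feature_vector <- function(image, pixel, spec = neighborhood_spec()) {
  gc <- directional_gradient_curves(image, pixel, spec)
  v <- numeric(0)
  for (ch in seq_along(gc$channels))
    for (ord in c("first", "second"))
      for (d in seq_len(4))
        v <- c(v, curve_descriptors(gc$channels[[ch]][[d]][[ord]]))
  names(v) <- feature_names_72()
  v
}

# vectorized descriptors over curve matrix (rows = pixels)
descriptors_matrix <- function(M) {
  A <- abs(M)
  n <- ncol(A)
  i1 <- max.col(A, ties.method = "first")
  mx <- A[cbind(seq_len(nrow(A)), i1)]
  A2 <- A; A2[cbind(seq_len(nrow(A)), i1)] <- -Inf
  i2 <- max.col(A2, ties.method = "first")
  mx2 <- A[cbind(seq_len(nrow(A)), i2)]
  P <- A[, 2:(n - 1), drop = FALSE] > A[, 1:(n - 2), drop = FALSE] &
    A[, 2:(n - 1), drop = FALSE] >= A[, 3:n, drop = FALSE]
  npk <- rowSums(P)
  first_pk <- max.col(P, ties.method = "first")  # column within P
  last_pk <- max.col(P, ties.method = "last")
  interval <- ifelse(npk >= 2, (last_pk - first_pk) / pmax(npk - 1, 1), 0)
  cbind(mx, mx2, interval)
}

#' Build the N x 72 texture feature matrix of a section
#'
#' Samples `n_pixels` positions uniformly without replacement from the image
#' interior (pixels at least r from every border), optionally restricted to a
#' foreground mask, and evaluates the 72 descriptors at each.
#'
#' @param image RGB section.
#' @param n_pixels number of sampled pixels.
#' @param spec `neighborhood_spec`.
#' @param seed integer seed; fixed seed gives an identical matrix.
#' @param mask optional logical matrix restricting eligible pixels.
#' @return list with `features` (n_pixels x 72 named matrix) and `coords`
#'   (n_pixels x 2, 0-based, in sampling order).
#' @export
build_feature_matrix <- function(image, n_pixels, spec = neighborhood_spec(),
                                 seed = 1L, mask = NULL) {
  stopifnot(n_pixels >= 1)
  r <- spec$r
  dims <- dim(image)
  if (dims[1] <= spec$side || dims[2] <= spec$side)
    abort("fascicle3d_config_error", "image smaller than the neighbourhood")
  eligible <- matrix(FALSE, dims[1], dims[2])
  eligible[(r + 1):(dims[1] - r), (r + 1):(dims[2] - r)] <- TRUE
  if (!is.null(mask)) eligible <- eligible & mask
  idx <- which(eligible)
  if (n_pixels > length(idx))
    abort("fascicle3d_config_error",
          sprintf("n_pixels = %d exceeds the %d eligible interior pixels",
                  n_pixels, length(idx)))
  pick <- with_seed(seed, sample(idx, n_pixels))
  coords <- cbind(row = (pick - 1L) %% dims[1], col = (pick - 1L) %/% dims[1])
  list(features = feature_matrix_at(image, coords, spec), coords = coords)
}

#' Evaluate the 72 texture descriptors at given pixel coordinates
#'
#' Vectorized workhorse behind [build_feature_matrix()]; useful when the
#' sampling positions are dictated externally (e.g. chosen in a registered
#' frame and mapped back onto the raw image so that texture is measured on
#' unresampled pixels).
#'
#' @param image RGB array.
#' @param coords n x 2 integer matrix of 0-based (row, col) positions, all at
#'   least r away from every border.
#' @param spec `neighborhood_spec`.
#' @return n x 72 named feature matrix.
#' @export
feature_matrix_at <- function(image, coords, spec = neighborhood_spec()) {
  r <- spec$r
  dims <- dim(image)
  mrow <- as.integer(coords[, 1]); mcol <- as.integer(coords[, 2])
  if (any(mrow < r | mcol < r | mrow > dims[1] - 1L - r |
            mcol > dims[2] - 1L - r))
    abort("fascicle3d_border_error", "coordinates closer than r to a border")
  n_pixels <- length(mrow)
  steps <- direction_steps()
  ks <- (-r):r
  blocks <- list()
  for (ch in 1:3) {
    chm <- image[, , ch]
    for (ord in 1:2) {
      for (d in seq_along(steps)) {
        st <- steps[[d]]
        # profile matrix: n_pixels x (2r+1)
        ri <- outer(mrow, ks * st[1], `+`) + 1L
        ci <- outer(mcol, ks * st[2], `+`) + 1L
        prof <- matrix(chm[cbind(as.vector(ri), as.vector(ci))],
                       nrow = n_pixels)
        M <- t(diff(t(prof)))
        if (ord == 2) M <- t(diff(t(M)))
        blocks[[length(blocks) + 1]] <- descriptors_matrix(M)
      }
    }
  }
  features <- do.call(cbind, blocks)
  colnames(features) <- feature_names_72()
  features
}

# ---------------------------------------------------------------------------
# Rough K-means (Lingras-West style): every point joins the lower
# approximation of its nearest cluster unless a second centre is nearly as
# close (distance ratio d2/d1 <= eps), in which case it joins the upper
# approximations of all such clusters.  Centres are updated as a weighted
# combination of the lower mean and the boundary (upper minus lower) mean.
# ---------------------------------------------------------------------------

#' Rough K-means clustering
#'
#' @param x n x d feature matrix.
#' @param k number of clusters.
#' @param w_lower,w_upper weights of the lower-approximation and boundary
#'   means in the centre update (must sum to 1, both > 0).
#' @param eps ambiguity ratio threshold: a point is ambiguous when
#'   d2/d1 <= eps (d1, d2 distances to the two nearest centres).  `eps = 0`
#'   reduces exactly to classical K-means from the same initialization;
#'   `"auto"` sets eps from the data as the 10% quantile of the observed
#'   d2/d1 ratios at initialization (at least 1).
#' @param seed integer seed for the initial centres (k distinct rows).
#' @param max_iter iteration cap; iteration stops when centres move < 1e-6.
#' @param nstart number of deterministic restarts (sub-seeds derived from
#'   `seed`); the run with the lowest within-cluster sum of squares wins.
#' @param scale if TRUE (default) feature columns are z-scored before
#'   clustering, balancing amplitude and interval descriptors; memberships
#'   are unaffected by the choice of units.  Reported centres are in the
#'   scaled space.
#' @return `rough_clustering`: `k`, `centers`, `lower` (cluster id per point,
#'   NA for ambiguous points), `upper` (list of point indices per cluster),
#'   `eps`, `w_lower`, `w_upper`, `iterations`.
#' @export
rough_kmeans <- function(x, k = 3L, w_lower = 0.7, w_upper = 0.3,
                         eps = 1.15, seed = 1L, max_iter = 100L,
                         scale = TRUE, nstart = 1L) {
  if (nstart > 1L) {
    runs <- lapply(seq_len(nstart), function(r)
      rough_kmeans(x, k = k, w_lower = w_lower, w_upper = w_upper, eps = eps,
                   seed = seed + 7919L * (r - 1L), max_iter = max_iter,
                   scale = scale, nstart = 1L))
    obj <- vapply(runs, function(cl) cl$objective, numeric(1))
    return(runs[[which.min(obj)]])
  }
  x <- rbind(x)
  if (isTRUE(scale)) {
    mu <- colMeans(x)
    sdv <- apply(x, 2, stats::sd)
    sdv[sdv < 1e-12] <- 1
    x <- sweep(sweep(x, 2, mu), 2, sdv, `/`)
  }
  if (abs(w_lower + w_upper - 1) > 1e-9 || w_lower <= 0 || w_upper <= 0)
    abort("fascicle3d_config_error", "w_lower + w_upper must equal 1, both > 0")
  ux <- unique(x)
  if (k > nrow(ux))
    abort("fascicle3d_config_error", "k exceeds the number of distinct rows")
  # k-means++ seeding: spread initial centres, deterministic under the seed
  centers <- with_seed(seed, {
    cen <- ux[sample(nrow(ux), 1), , drop = FALSE]
    while (nrow(cen) < k) {
      d2 <- apply(outer(rowSums(ux^2), rowSums(cen^2), `+`) -
                    2 * tcrossprod(ux, cen), 1, min)
      d2 <- pmax(d2, 0)
      p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / nrow(ux), nrow(ux))
      cen <- rbind(cen, ux[sample(nrow(ux), 1, prob = p), ])
    }
    cen
  })

  dist2 <- function(cen) {
    outer(rowSums(x^2), rowSums(cen^2), `+`) - 2 * tcrossprod(x, cen)
  }
  if (identical(eps, "auto")) {
    d2m <- dist2(centers)
    srt <- t(apply(d2m, 1, sort))
    ratio <- sqrt(pmax(srt[, 2], 0)) / pmax(sqrt(pmax(srt[, 1], 0)), 1e-12)
    eps <- max(1, unname(quantile(ratio, 0.10)))
  }

  iterations <- 0L
  for (it in seq_len(max_iter)) {
    iterations <- it
    d2m <- pmax(dist2(centers), 0)
    nearest <- max.col(-d2m, ties.method = "first")
    d1 <- sqrt(d2m[cbind(seq_len(nrow(x)), nearest)])
    ambiguous_with <- lapply(seq_len(nrow(x)), function(i) {
      di <- sqrt(d2m[i, ])
      near <- which(di <= eps * max(d1[i], 1e-12) + 1e-15)
      near <- union(nearest[i], near)
      near
    })
    n_amb <- lengths(ambiguous_with)
    lower <- ifelse(n_amb == 1L, nearest, NA_integer_)
    upper <- lapply(seq_len(k), function(c.)
      which(vapply(ambiguous_with, function(s) c. %in% s, logical(1))))

    new_centers <- centers
    for (c. in seq_len(k)) {
      lo <- which(!is.na(lower) & lower == c.)
      bd <- setdiff(upper[[c.]], lo)
      if (length(lo) > 0 && length(bd) > 0) {
        new_centers[c., ] <- w_lower * colMeans(x[lo, , drop = FALSE]) +
          w_upper * colMeans(x[bd, , drop = FALSE])
      } else if (length(lo) > 0) {
        new_centers[c., ] <- colMeans(x[lo, , drop = FALSE])
      } else if (length(upper[[c.]]) > 0) {
        new_centers[c., ] <- colMeans(x[upper[[c.]], , drop = FALSE])
      }
    }
    moved <- max(sqrt(rowSums((new_centers - centers)^2)))
    centers <- new_centers
    if (moved < 1e-6) break
  }
  # final memberships at the converged centres
  d2m <- pmax(dist2(centers), 0)
  nearest <- max.col(-d2m, ties.method = "first")
  d1 <- sqrt(d2m[cbind(seq_len(nrow(x)), nearest)])
  ambiguous_with <- lapply(seq_len(nrow(x)), function(i) {
    di <- sqrt(d2m[i, ])
    union(nearest[i], which(di <= eps * max(d1[i], 1e-12) + 1e-15))
  })
  n_amb <- lengths(ambiguous_with)
  lower <- ifelse(n_amb == 1L, nearest, NA_integer_)
  upper <- lapply(seq_len(k), function(c.)
    which(vapply(ambiguous_with, function(s) c. %in% s, logical(1))))
  objective <- sum(d2m[cbind(seq_len(nrow(x)), nearest)])
  structure(list(k = k, centers = centers, lower = lower, upper = upper,
                 eps = eps, w_lower = w_lower, w_upper = w_upper,
                 iterations = iterations, objective = objective),
            class = "rough_clustering")
}

#' Name texture clusters by darkness
#'
#' The cluster whose member pixels are darkest (mean grayscale) is sensory,
#' the lightest is motor, the middle one mixed.
#'
#' @param clustering `rough_clustering` with k = 3.
#' @param gray_values grayscale value per clustered pixel.
#' @return character vector: type name per cluster id.
#' @export
cluster_type_names <- function(clustering, gray_values) {
  k <- clustering$k
  means <- vapply(seq_len(k), function(c.) {
    memb <- which(!is.na(clustering$lower) & clustering$lower == c.)
    if (length(memb) == 0) memb <- clustering$upper[[c.]]
    if (length(memb) == 0) return(Inf)
    mean(gray_values[memb])
  }, numeric(1))
  if (k != 3) return(paste0("cluster", rank(means, ties.method = "first")))
  types <- character(k)
  ord <- order(means)
  types[ord] <- c("sensory", "mixed", "motor")
  types
}

#' Label fascicle contours with functional types
#'
#' Each contour is labelled by majority vote of the lower-approximation
#' cluster labels of the sampled pixels falling inside it; clusters are named
#' by darkness ([cluster_type_names()]).  A vote tie labels the fascicle
#' `"mixed"`; a contour containing no sampled pixel is labelled `"unknown"`
#' with a warning.
#'
#' @param contours list of closed polygons (n x 2 matrices, (row, col)).
#' @param clustering `rough_clustering` of the sampled pixels.
#' @param coords sampled pixel coordinates (rows parallel to the clustering).
#' @param image the section (for grayscale darkness ranking).
#' @return list with `types` (character per contour) and `cluster_types`.
#' @export
label_fascicles <- function(contours, clustering, coords, image) {
  gray <- rgb_to_gray(image)
  gvals <- gray[cbind(coords[, 1] + 1L, coords[, 2] + 1L)]
  ctypes <- cluster_type_names(clustering, gvals)
  types <- character(length(contours))
  for (i in seq_along(contours)) {
    poly <- contours[[i]]
    if (is.null(poly)) { types[i] <- "unknown"; next }
    inside <- point_in_polygon(coords, poly)
    labs <- clustering$lower[inside]
    labs <- labs[!is.na(labs)]
    if (length(labs) == 0) {
      warning(sprintf("contour %d contains no sampled pixels; labelled unknown", i))
      types[i] <- "unknown"
      next
    }
    tab <- table(ctypes[labs])
    winners <- names(tab)[tab == max(tab)]
    types[i] <- if (length(winners) == 1) winners else "mixed"
  }
  list(types = types, cluster_types = ctypes)
}
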