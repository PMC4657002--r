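# ---------------------------------------------------------------------------
# Landmark-based registration with an exactly determined bilinear transform.
#
# A bilinear transform maps (row, col) -> (row', col') with
#   row' = a0 + a1*row + a2*col + a3*row*col
#   col' = b0 + b1*row + b2*col + b3*row*col
# and is fixed uniquely by four control-point pairs in general position
# (one 4x4 linear solve per output coordinate).
# ---------------------------------------------------------------------------

#' Construct a bilinear coordinate transform
#' @param a,b numeric length-4 coefficient vectors (a0..a3, b0..b3) for the
#'   row and column output coordinate respectively.
#' @return object of class `bilinear_transform`.
#' @export
bilinear_transform <- function(a, b) {
  stopifnot(length(a) == 4, length(b) == 4)
  structure(list(a = as.numeric(a), b = as.numeric(b)),
            class = "bilinear_transform")
}

#' Identity bilinear transform
#' @return transform with coefficients (0,1,0,0) and (0,0,1,0).
#' @export
bilinear_identity <- function() bilinear_transform(c(0, 1, 0, 0), c(0, 0, 1, 0))

#' Apply a bilinear transform to points
#' @param t `bilinear_transform`.
#' @param pts n x 2 matrix of (row, col) coordinates.
#' @return n x 2 matrix of transformed coordinates.
#' @export
apply_bilinear <- function(t, pts) {
  pts <- rbind(pts)  # accept a bare length-2 vector
  r <- pts[, 1]; c <- pts[, 2]
  cbind(t$a[1] + t$a[2] * r + t$a[3] * c + t$a[4] * r * c,
        t$b[1] + t$b[2] * r + t$b[3] * c + t$b[4] * r * c)
}

#' Numerically invert a bilinear transform at given points
#'
#' Newton iteration on the 2 x 2 Jacobian; converges in a few steps for the
#' mild transforms produced by section misalignment.
#'
#' @param t `bilinear_transform`.
#' @param pts n x 2 target points (in the output frame of `t`).
#' @param iters Newton steps.
#' @return n x 2 matrix `p` with `apply_bilinear(t, p) == pts`.
#' @export
invert_bilinear_at <- function(t, pts, iters = 8L) {
  pts <- rbind(pts)
  p <- pts  # initial guess: transform is close to identity
  for (it in seq_len(iters)) {
    q <- apply_bilinear(t, p)
    er <- pts[, 1] - q[, 1]; ec <- pts[, 2] - q[, 2]
    j11 <- t$a[2] + t$a[4] * p[, 2]; j12 <- t$a[3] + t$a[4] * p[, 1]
    j21 <- t$b[2] + t$b[4] * p[, 2]; j22 <- t$b[3] + t$b[4] * p[, 1]
    det <- j11 * j22 - j12 * j21
    p <- p + cbind((j22 * er - j12 * ec) / det,
                   (-j21 * er + j11 * ec) / det)
  }
  p
}

#' Fit the bilinear transform through four control-point pairs
#'
#' Solves the exactly determined 4 x 4 system so that every moving point maps
#' onto its reference partner (residual at machine precision).  Points are
#' matched by row name when both matrices carry the canonical labels
#' S_a..S_d, otherwise by row order.
#'
#' @param reference_points,moving_points 4 x 2 matrices of (row, col).
#' @return `bilinear_transform` `t` with `apply_bilinear(t, moving) == reference`.
#' @export
fit_bilinear <- function(reference_points, moving_points) {
  stopifnot(nrow(reference_points) == 4, nrow(moving_points) == 4)
  if (!is.null(rownames(reference_points)) &&
      !is.null(rownames(moving_points)) &&
      setequal(rownames(reference_points), rownames(moving_points))) {
    moving_points <- moving_points[rownames(reference_points), , drop = FALSE]
  }
  r <- moving_points[, 1]; c <- moving_points[, 2]
  M <- cbind(1, r, c, r * c)
  if (rcond(M) < 1e-12)
    abort("fascicle3d_singular_geometry",
          "control points are in a degenerate configuration")
  a <- solve(M, reference_points[, 1])
  b <- solve(M, reference_points[, 2])
  bilinear_transform(a, b)
}

modal_border_color <- function(image) {
  gray <- is.matrix(image)
  pick <- function(ch) {
    border <- c(ch[1, ], ch[nrow(ch), ], ch[, 1], ch[, ncol(ch)])
    q <- round(border * 64) / 64
    as.numeric(names(sort(table(q), decreasing = TRUE))[1])
  }
  if (gray) pick(image) else vapply(1:3, function(k) pick(image[, , k]),
                                    numeric(1))
}

#' Warp a section image with a bilinear transform
#'
#' Backward mapping: the transform is interpreted as the map from output
#' (registered-frame) pixel coordinates to source-image coordinates, and the
#' source is sampled with bilinear intensity interpolation.  Out-of-frame
#' pixels take `fill` (default: modal border colour of the source).
#'
#' @param image RGB array or grayscale matrix.
#' @param t `bilinear_transform` (output -> source coordinates).
#' @param fill fill value(s); NULL for the modal border colour.
#' @return image of the same size and kind.
#' @export
warp_section <- function(image, t, fill = NULL) {
  gray <- is.matrix(image)
  rows <- if (gray) nrow(image) else dim(image)[1]
  cols <- if (gray) ncol(image) else dim(image)[2]
  if (is.null(fill)) fill <- modal_border_color(image)
  PR <- matrix(rep(0:(rows - 1), cols), rows, cols)
  PC <- matrix(rep(0:(cols - 1), each = rows), rows, cols)
  src <- apply_bilinear(t, cbind(as.vector(PR), as.vector(PC)))
  if (gray) {
    return(matrix(bilinear_sample(image, src[, 1], src[, 2], fill[1]),
                  rows, cols))
  }
  out <- array(0, c(rows, cols, 3))
  fill <- rep_len(fill, 3)
  for (ch in 1:3)
    out[, , ch] <- matrix(bilinear_sample(image[, , ch], src[, 1], src[, 2],
                                          fill[ch]), rows, cols)
  out
}

#' Register a stack of sections to a common frame
#'
#' Fits, per section, the bilinear transform carrying its four landmark
#' centres onto those of the reference section, and resamples every image
#' into the reference frame.  Sections with a missing landmark set are
#' skipped with a warning and reported as gaps (mirroring the discarding of
#' failed sections during specimen preparation).
#'
#' @param stack list of section images.
#' @param landmarks list of `landmark_set` objects (or NULL for a gap),
#'   parallel to `stack`.
#' @param reference_index 0-based index of the anchor section (default 0).
#' @return list with `registered` (list of images; gap sections NULL),
#'   `transforms` (list of moving-to-reference `bilinear_transform`s, identity
#'   for the reference; NULL for gaps), `backward` (reference-to-moving
#'   transforms actually used for resampling) and `gaps` (0-based indices
#'   skipped).
#' @export
register_stack <- function(stack, landmarks, reference_index = 0L) {
  n <- length(stack)
  stopifnot(length(landmarks) == n, reference_index >= 0, reference_index < n)
  ref <- landmarks[[reference_index + 1L]]
  if (is.null(ref))
    abort("fascicle3d_registration_error",
          "reference section has no landmark set")
  registered <- vector("list", n)
  transforms <- vector("list", n)
  backward <- vector("list", n)
  gaps <- integer(0)
  for (s in seq_len(n)) {
    lm <- landmarks[[s]]
    if (is.null(lm)) {
      warning(sprintf("section %d has no landmarks; skipped (gap)", s - 1L))
      gaps <- c(gaps, s - 1L)
      next
    }
    if (s == reference_index + 1L) {
      registered[[s]] <- stack[[s]]
      transforms[[s]] <- bilinear_identity()
      backward[[s]] <- bilinear_identity()
      next
    }
    transforms[[s]] <- fit_bilinear(ref$centers, lm$centers)
    backward[[s]] <- fit_bilinear(lm$centers, ref$centers)
    registered[[s]] <- warp_section(stack[[s]], backward[[s]])
  }
  list(registered = registered, transforms = transforms, backward = backward,
       gaps = gaps)
}
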