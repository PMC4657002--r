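# ---------------------------------------------------------------------------
# Position-line recognition.
#
# The four fiducial threads embedded beside the specimen appear in every
# section as dark, circle-like dots 12-15 px across.  Candidate dark blobs
# are screened by size, the surrounding 15 x 15 window is classified
# circle-like / non-circular by a trained LS-SVM, and the surviving four
# detections become the section's labelled landmark set.
# ---------------------------------------------------------------------------

#' The 15 x 15 ring template
#'
#' The annular band "B" collects the pixels where the edge of a true
#' position-line cross section may fall: distance from the window centre
#' (7, 7) within [5.0, 7.6] px (calibrated to blob diameters 12-15 px; the
#' exact band geometry is a package choice).
#'
#' @return list with `size` (15), logical `band_mask` and `center_index`
#'   `c(7, 7)` (0-based).
#' @export
ring_template <- function() {
  rr <- matrix(rep(0:14, 15), 15, 15)
  cc <- matrix(rep(0:14, each = 15), 15, 15)
  d <- sqrt((rr - 7)^2 + (cc - 7)^2)
  list(size = 15L, band_mask = d >= 5.0 & d <= 7.6, center_index = c(7L, 7L))
}

#' Train the position-line window classifier
#'
#' @param windows a `template_set` from [generate_template_windows()] (or any
#'   list with `features` and `y`).
#' @param sigma2,gamma LS-SVM hyperparameters.  The defaults are a robust
#'   broad-kernel configuration; `(sigma2 = 2, gamma = 100)` is the
#'   conventional untuned baseline that genetic-algorithm tuning is measured
#'   against.
#' @return `lssvm_model`.
#' @export
train_detector <- function(windows, sigma2 = 20, gamma = 100) {
  lssvm_train(windows$features, windows$y, sigma2, gamma)
}

#' Tune the detector hyperparameters with a genetic algorithm
#'
#' Fitness is the misclassification rate on the held-out window set; the
#' search is warm-started at the conventional baseline (sigma2 = 2,
#' gamma = 100) so the tuned error never exceeds it.
#'
#' @param train_windows,test_windows `template_set`s.
#' @param ga_config list with optional `pop_size`, `generations`, `bounds`
#'   (2 x 2 matrix rows = (lower, upper) for (sigma2, gamma)) and `seed`.
#' @return list with `sigma2`, `gamma`, `test_error` and the GA `history`.
#' @export
tune_detector <- function(train_windows, test_windows,
                          ga_config = list()) {
  if (length(test_windows$y) == 0)
    abort("fascicle3d_config_error", "empty test set")
  cfg <- utils::modifyList(list(pop_size = 30L, generations = 50L,
                                bounds = rbind(lower = c(0.1, 1),
                                               upper = c(50, 1000)),
                                seed = 1L), ga_config)
  fn <- function(par) {
    m <- lssvm_train(train_windows$features, train_windows$y, par[1], par[2])
    lssvm_error(m, test_windows$features, test_windows$y)
  }
  res <- ga_minimize(fn, cfg$bounds[1, ], cfg$bounds[2, ],
                     pop_size = cfg$pop_size, generations = cfg$generations,
                     seed = cfg$seed, seed_points = rbind(c(2, 100)))
  list(sigma2 = res$par[1], gamma = res$par[2], test_error = res$value,
       history = res$history)
}

#' Assemble a labelled landmark set
#'
#' Canonical labelling: the four centres are ordered counterclockwise (in
#' standard orientation, i.e. x = col, y = -row) by angle around their
#' centroid, starting from the smallest non-negative angle, and labelled
#' S_a..S_d.  This makes correspondences stable across sections.
#'
#' @param centers 4 x 2 matrix of (row, col) centres.
#' @param section_index 0-based section index.
#' @return `landmark_set`: list with `section_index`, labelled `centers` and
#'   `section_center` (their centroid).
#' @export
landmark_set <- function(centers, section_index = 0L) {
  stopifnot(nrow(centers) == 4)
  ctr <- colMeans(centers)
  ang <- atan2(-(centers[, 1] - ctr[1]), centers[, 2] - ctr[2])
  ang <- ang %% (2 * pi)
  ord <- order(ang)
  centers <- centers[ord, , drop = FALSE]
  rownames(centers) <- c("S_a", "S_b", "S_c", "S_d")
  structure(list(section_index = as.integer(section_index),
                 centers = centers, section_center = ctr),
            class = "landmark_set")
}

#' Detect the four position-line cross sections in one image
#'
#' A darkness threshold plus connected-component size screen proposes
#' candidate blobs; each candidate's 15 x 15 window is scored by the LS-SVM
#' and detections are reduced by non-maximum suppression (radius 8 px,
#' highest decision value wins, lexicographic tie-break).  Exactly four
#' survivors are required -- anything else raises a
#' `fascicle3d_detection_count_error` carrying the found count, signalling a
#' failed (incomplete-morphology) section.
#'
#' @param image RGB section image.
#' @param model trained `lssvm_model`.
#' @param darkness grayscale threshold below which pixels are candidate-dark.
#' @param area_range admissible component pixel counts; deliberately wider
#'   than the ideal disk areas so that no true landmark is screened out
#'   before classification.
#' @param nms_radius suppression radius in px.
#' @return `landmark_set`.
#' @export
detect_position_lines <- function(image, model, darkness = 0.45,
                                  area_range = c(80, 230), nms_radius = 8) {
  gray <- rgb_to_gray(image)
  rows <- nrow(gray); cols <- ncol(gray)
  if (rows < 15 || cols < 15)
    abort("fascicle3d_config_error", "image smaller than the 15x15 template")
  mask <- gray < darkness
  stats <- component_stats(connected_components(mask))
  cand <- stats[stats$size >= area_range[1] & stats$size <= area_range[2] &
                  stats$height <= 22 & stats$width <= 22, , drop = FALSE]
  dets <- NULL
  if (nrow(cand) > 0) {
    rc <- round(cand$row); cc <- round(cand$col)
    ok <- rc >= 7 & cc >= 7 & rc <= rows - 8 & cc <= cols - 8
    rc <- rc[ok]; cc <- cc[ok]
    if (length(rc) > 0) {
      wins <- lapply(seq_along(rc), function(i)
        image[(rc[i] - 7):(rc[i] + 7) + 1L, (cc[i] - 7):(cc[i] + 7) + 1L, ,
              drop = FALSE])
      feats <- window_features(wins)
      score <- lssvm_decision(model, feats)
      keep <- score > 0
      dets <- data.frame(row = rc[keep], col = cc[keep],
                         score = score[keep])
    }
  }
  if (!is.null(dets) && nrow(dets) > 1) {
    ord <- order(-dets$score, dets$row, dets$col)
    dets <- dets[ord, , drop = FALSE]
    keep_rows <- integer(0)
    for (i in seq_len(nrow(dets))) {
      if (length(keep_rows) > 0) {
        d <- sqrt((dets$row[keep_rows] - dets$row[i])^2 +
                    (dets$col[keep_rows] - dets$col[i])^2)
        if (any(d <= nms_radius)) next
      }
      keep_rows <- c(keep_rows, i)
    }
    dets <- dets[keep_rows, , drop = FALSE]
  }
  found <- if (is.null(dets)) 0L else nrow(dets)
  if (found != 4L)
    abort("fascicle3d_detection_count_error",
          sprintf("expected 4 position lines, found %d", found),
          count = found)
  landmark_set(cbind(dets$row, dets$col), 0L)
}

#' Persist a trained detector as a JSON archive
#' @param model `lssvm_model`.
#' @param path output file.
#' @export
save_detector <- function(model, path) {
  jsonlite::write_json(list(
    format = "fascicle3d-lssvm", version = 1L,
    sigma2 = model$sigma2, gamma = model$gamma,
    alpha = model$alpha, b = model$b,
    normalization = model$normalization,
    n = nrow(model$x), d = ncol(model$x),
    x = as.vector(model$x)
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a detector archive written by [save_detector()]
#' @param path JSON file.
#' @return `lssvm_model`.
#' @export
load_detector <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(j$format) || j$format != "fascicle3d-lssvm")
    abort("fascicle3d_format_error", "not a fascicle3d detector archive")
  structure(list(alpha = j$alpha, b = j$b,
                 x = matrix(j$x, j$n, j$d),
                 sigma2 = j$sigma2, gamma = j$gamma,
                 normalization = j$normalization),
            class = "lssvm_model")
}
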