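# ---------------------------------------------------------------------------
# One-command orchestration: detect -> register -> segment -> classify ->
# reconstruct, with per-stage artifacts, a structured log and a checksum
# manifest.  Every stage can also be re-run from the previous stage's
# on-disk artifact through the exported read/write helpers.
# ---------------------------------------------------------------------------

default_pipeline_params <- function() {
  list(
    detector = list(n_pos = 120L, n_neg = 120L, sigma2 = 20, gamma = 100,
                    tune = FALSE, darkness = 0.45),
    ga = list(pop_size = 16L, generations = 12L),
    registration = list(reference_index = 0L),
    segmentation = list(blur_sigma = 2.5, min_size = 30, split_sigma = 23,
                        merge_dist = 34),
    snake = list(alpha = 0.1, beta = 0.5, step = 1.0, max_iter = 200L,
                 mode = "improved", n_vertices = 100L, mu = 0.2,
                 gvf_iter = 80L),
    typing = list(r = 11L, n_pixels_per_section = 2000L, eps = 1.15,
                  w_lower = 0.7, w_upper = 0.3, nstart = 6L),
    reconstruction = list(jaccard_min = 0.2, z_spacing_mm = 0.5,
                          n_ring = 100L, labelmap = TRUE)
  )
}

#' Pipeline configuration
#'
#' @param stack_dir directory of ASCII PPM section images.
#' @param out_dir output directory for all artifacts.
#' @param seed global seed; propagated to every stochastic stage.
#' @param params nested list of per-stage parameter overrides; see
#'   `fascicle3d:::default_pipeline_params()`.
#' @return `pipeline_config` object.
#' @export
pipeline_config <- function(stack_dir, out_dir, seed = 1L, params = list()) {
  structure(list(stack_dir = stack_dir, out_dir = out_dir,
                 seed = as.integer(seed),
                 params = utils::modifyList(default_pipeline_params(), params)),
            class = "pipeline_config")
}

#' Print (or return) the default flat-text pipeline configuration
#' @param file optional path to write to; "" prints to stdout.
#' @return invisible character vector of config lines.
#' @export
print_default_config <- function(file = "") {
  p <- default_pipeline_params()
  lines <- c("# fascicle3d pipeline defaults (key = value, sectioned per stage)")
  for (stage in names(p)) {
    lines <- c(lines, sprintf("[%s]", stage))
    for (k in names(p[[stage]]))
      lines <- c(lines, sprintf("%s = %s", k, format(p[[stage]][[k]])))
    lines <- c(lines, "")
  }
  if (nzchar(file)) writeLines(lines, file) else writeLines(lines)
  invisible(lines)
}

#' Read a flat key = value pipeline config file
#' @param path config file with `[stage]` sections.
#' @return nested parameter list suitable for [pipeline_config()].
#' @export
read_config_file <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  params <- list()
  stage <- NULL
  for (ln in lines) {
    if (grepl("^\\[.*\\]$", ln)) {
      stage <- gsub("^\\[|\\]$", "", ln)
      params[[stage]] <- list()
    } else if (grepl("=", ln) && !is.null(stage)) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      key <- trimws(kv[1]); val <- trimws(paste(kv[-1], collapse = "="))
      num <- suppressWarnings(as.numeric(val))
      params[[stage]][[key]] <-
        if (!is.na(num)) num
        else if (val %in% c("TRUE", "FALSE")) as.logical(val)
        else val
    }
  }
  params
}

# landmark CSV interface (columns: section, label, row, col; 0-based) --------

#' Write landmark sets to CSV
#' @param landmarks list of `landmark_set` (NULL entries skipped).
#' @param path output CSV.
#' @export
write_landmarks_csv <- function(landmarks, path) {
  rows <- list()
  for (s in seq_along(landmarks)) {
    lm <- landmarks[[s]]
    if (is.null(lm)) next
    rows[[length(rows) + 1]] <- data.frame(
      section = s - 1L, label = rownames(lm$centers),
      row = lm$centers[, 1], col = lm$centers[, 2])
  }
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read landmark sets from CSV
#' @param path CSV from [write_landmarks_csv()].
#' @param n_sections total stack length (gap sections come back NULL).
#' @return list of `landmark_set`.
#' @export
read_landmarks_csv <- function(path, n_sections = NULL) {
  df <- read.csv(path)
  if (is.null(n_sections)) n_sections <- max(df$section) + 1L
  out <- vector("list", n_sections)
  for (s in unique(df$section)) {
    sub <- df[df$section == s, ]
    centers <- as.matrix(sub[, c("row", "col")])
    rownames(centers) <- sub$label
    out[[s + 1L]] <- landmark_set(centers[c("S_a", "S_b", "S_c", "S_d"), ],
                                  section_index = s)
  }
  out
}

#' Write per-section transforms to CSV (section, a0..a3, b0..b3)
#' @param transforms list of `bilinear_transform` (NULL entries skipped).
#' @param path output CSV.
#' @export
write_transforms_csv <- function(transforms, path) {
  rows <- list()
  for (s in seq_along(transforms)) {
    t <- transforms[[s]]
    if (is.null(t)) next
    rows[[length(rows) + 1]] <- data.frame(
      section = s - 1L, a0 = t$a[1], a1 = t$a[2], a2 = t$a[3], a3 = t$a[4],
      b0 = t$b[1], b1 = t$b[2], b2 = t$b[3], b3 = t$b[4])
  }
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

# contours JSON interface -----------------------------------------------------

#' Write per-section contours (and cluster centers) to JSON
#' @param contour_sections list (per section) of polygon lists.
#' @param centers optional list of k x 2 centre matrices.
#' @param image_size (rows, cols) recorded for downstream rasterization.
#' @param path output JSON.
#' @export
write_contours_json <- function(contour_sections, path, centers = NULL,
                                image_size = NULL) {
  out <- list(image_size = image_size,
              sections = lapply(seq_along(contour_sections), function(s) {
                polys <- contour_sections[[s]]
                list(section = s - 1L,
                     contours = lapply(polys, function(p) {
                       if (is.null(p)) return(NULL)
                       list(row = p[, 1], col = p[, 2])
                     }),
                     centers = if (!is.null(centers)) {
                       cm <- centers[[s]]
                       list(row = cm[, 1], col = cm[, 2])
                     })
              }))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a contours JSON written by [write_contours_json()]
#' @param path JSON file.
#' @return list with `image_size` and `contour_sections`.
#' @export
read_contours_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  contour_sections <- lapply(j$sections, function(sec)
    lapply(sec$contours, function(p)
      if (is.null(p)) NULL else cbind(row = unlist(p$row), col = unlist(p$col))))
  list(image_size = unlist(j$image_size), contour_sections = contour_sections)
}

stage_logger <- function(log_path) {
  function(stage, ...) {
    msg <- sprintf("stage=%s %s", stage,
                   paste(sprintf("%s=%s", names(list(...)),
                                 vapply(list(...), format, "")), collapse = " "))
    cat(msg, "\n", file = log_path, append = TRUE)
    message(msg)
  }
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort("fascicle3d_stage_error",
          sprintf("pipeline halted at stage '%s': %s", name,
                  conditionMessage(e)), stage = name)
  })
}

#' Run the full reconstruction pipeline
#'
#' Executes detect -> register -> segment -> classify -> reconstruct on the
#' PPM stack in `config$stack_dir`, writing `landmarks.csv`,
#' `transforms.csv`, `contours.json`, `types.json`, `model.ply` (and a
#' labelmap directory) plus `pipeline.log` into `config$out_dir`.  A rerun
#' with identical config and seed reproduces identical checksums for the
#' deterministic artifacts.  Any stage failure halts with the stage name;
#' artifacts of completed stages are preserved.
#'
#' @param config `pipeline_config`.
#' @return manifest data.frame (artifact, path, md5).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!dir.exists(config$stack_dir))
    abort("fascicle3d_config_error",
          paste("stack directory does not exist:", config$stack_dir))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- config$params
  log <- stage_logger(file.path(config$out_dir, "pipeline.log"))
  artifacts <- list()

  stack <- run_stage("load", read_stack(config$stack_dir))
  n <- length(stack)
  image_size <- dim(stack[[1]])[1:2]
  log("load", sections = n)

  # --- detect ---------------------------------------------------------------
  landmarks <- run_stage("detect", {
    wins <- generate_template_windows(p$detector$n_pos, p$detector$n_neg,
                                      seed = config$seed)
    model <- train_detector(wins, p$detector$sigma2, p$detector$gamma)
    lms <- vector("list", n)
    for (s in seq_len(n)) {
      lms[[s]] <- tryCatch({
        lm <- detect_position_lines(stack[[s]], model,
                                    darkness = p$detector$darkness)
        lm$section_index <- s - 1L
        lm
      }, fascicle3d_detection_count_error = function(e) {
        warning(sprintf("section %d: %s", s - 1L, conditionMessage(e)))
        NULL
      })
    }
    lms
  })
  lm_path <- file.path(config$out_dir, "landmarks.csv")
  write_landmarks_csv(landmarks, lm_path)
  artifacts$landmarks <- lm_path
  log("detect", found = sum(!vapply(landmarks, is.null, logical(1))))

  # --- register -------------------------------------------------------------
  reg <- run_stage("register",
                   register_stack(stack, landmarks,
                                  p$registration$reference_index))
  tr_path <- file.path(config$out_dir, "transforms.csv")
  write_transforms_csv(reg$transforms, tr_path)
  artifacts$transforms <- tr_path
  log("register", gaps = length(reg$gaps))

  # --- segment --------------------------------------------------------------
  seg <- run_stage("segment", {
    contour_sections <- vector("list", n)
    centers <- vector("list", n)
    masks <- vector("list", n)
    for (s in seq_len(n)) {
      img <- reg$registered[[s]]
      if (is.null(img)) { contour_sections[[s]] <- list(); next }
      fg <- preprocess_section(img, blur_sigma = p$segmentation$blur_sigma,
                               min_size = p$segmentation$min_size)
      pts <- mask_points(fg)
      cl <- cluster_fascicle_pixels(pts,
                                    split_sigma = p$segmentation$split_sigma,
                                    merge_dist = p$segmentation$merge_dist)
      sn <- extract_fascicle_contours(img, cl, pts, snake_params = p$snake)
      contour_sections[[s]] <- lapply(sn, function(x)
        if (is.null(x)) NULL else x$vertices)
      centers[[s]] <- cl$centers
      masks[[s]] <- fg
    }
    list(contour_sections = contour_sections, centers = centers,
         masks = masks)
  })
  ct_path <- file.path(config$out_dir, "contours.json")
  write_contours_json(seg$contour_sections, ct_path, centers = seg$centers,
                      image_size = image_size)
  artifacts$contours <- ct_path
  log("segment",
      contours = sum(lengths(seg$contour_sections)))

  # --- classify -------------------------------------------------------------
  typed <- run_stage("classify", {
    spec <- neighborhood_spec(p$typing$r)
    r <- spec$r
    feats <- list(); coords <- list(); sec_of <- list(); grays <- list()
    for (s in seq_len(n)) {
      img <- reg$registered[[s]]
      if (is.null(img) || length(seg$contour_sections[[s]]) == 0) next
      # sample in the registered frame (where contours live) but measure the
      # texture on the raw, unresampled section: interpolation during
      # warping dilutes granule amplitudes unevenly across sections
      eligible <- matrix(FALSE, image_size[1], image_size[2])
      eligible[(r + 1):(image_size[1] - r), (r + 1):(image_size[2] - r)] <- TRUE
      eligible <- eligible & seg$masks[[s]]
      idx <- which(eligible)
      if (length(idx) == 0) next
      n_samp <- min(p$typing$n_pixels_per_section, length(idx))
      pick <- with_seed(config$seed + s, sample(idx, n_samp))
      co_reg <- cbind(row = (pick - 1L) %% image_size[1],
                      col = (pick - 1L) %/% image_size[1])
      co_raw <- round(apply_bilinear(reg$backward[[s]], co_reg))
      ok <- co_raw[, 1] >= r & co_raw[, 2] >= r &
        co_raw[, 1] <= image_size[1] - 1L - r &
        co_raw[, 2] <= image_size[2] - 1L - r
      if (!any(ok)) next
      co_reg <- co_reg[ok, , drop = FALSE]
      co_raw <- co_raw[ok, , drop = FALSE]
      feats[[length(feats) + 1]] <- feature_matrix_at(stack[[s]], co_raw, spec)
      coords[[length(coords) + 1]] <- co_reg
      sec_of[[length(sec_of) + 1]] <- rep(s, nrow(co_reg))
      g <- rgb_to_gray(stack[[s]])
      grays[[length(grays) + 1]] <- g[cbind(co_raw[, 1] + 1L,
                                            co_raw[, 2] + 1L)]
    }
    X <- do.call(rbind, feats)
    sec_vec <- unlist(sec_of)
    cl <- rough_kmeans(X, k = 3L, w_lower = p$typing$w_lower,
                       w_upper = p$typing$w_upper, eps = p$typing$eps,
                       seed = config$seed, nstart = p$typing$nstart)
    ctypes <- cluster_type_names(cl, unlist(grays))
    types <- vector("list", n)
    for (s in seq_len(n)) {
      polys <- seg$contour_sections[[s]]
      if (length(polys) == 0) { types[[s]] <- character(0); next }
      sel <- sec_vec == s
      co <- do.call(rbind, coords)[sel, , drop = FALSE]
      lab <- cl$lower[sel]
      ty <- character(length(polys))
      for (i in seq_along(polys)) {
        if (is.null(polys[[i]])) { ty[i] <- "unknown"; next }
        inside <- point_in_polygon(co, polys[[i]])
        labs <- lab[inside]; labs <- labs[!is.na(labs)]
        if (length(labs) == 0) { ty[i] <- "unknown"; next }
        tab <- table(ctypes[labs])
        winners <- names(tab)[tab == max(tab)]
        ty[i] <- if (length(winners) == 1) winners else "mixed"
      }
      types[[s]] <- ty
    }
    types
  })
  ty_path <- file.path(config$out_dir, "types.json")
  jsonlite::write_json(typed, ty_path, auto_unbox = FALSE, digits = NA)
  artifacts$types <- ty_path
  log("classify", typed = sum(lengths(typed)))

  # --- reconstruct ----------------------------------------------------------
  model_path <- file.path(config$out_dir, "model.ply")
  meshes <- run_stage("reconstruct", {
    linkage <- link_contours(seg$contour_sections, image_size,
                             jaccard_min = p$reconstruction$jaccard_min,
                             types = typed)
    meshes <- build_meshes(linkage, seg$contour_sections,
                           z_spacing_mm = p$reconstruction$z_spacing_mm,
                           n_ring = p$reconstruction$n_ring)
    write_ply(meshes, model_path)
    write_obj(meshes, file.path(config$out_dir, "model.obj"))
    if (isTRUE(p$reconstruction$labelmap))
      export_labelmap(seg$contour_sections, image_size,
                      file.path(config$out_dir, "labelmap"))
    meshes
  })
  artifacts$model <- model_path
  log("reconstruct", meshes = length(meshes))

  manifest <- data.frame(
    artifact = names(artifacts),
    path = unlist(artifacts),
    md5 = vapply(unlist(artifacts), function(f)
      unname(tools::md5sum(f)), ""),
    row.names = NULL)
  write.csv(manifest, file.path(config$out_dir, "manifest.csv"),
            row.names = FALSE)
  manifest
}
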