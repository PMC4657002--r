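# ---------------------------------------------------------------------------
# Synthetic histology generator.
#
# Emulates H&E-stained serial cross sections of a peripheral nerve: fascicles
# appear as regions of discrete dark granules separated by unstained voids,
# four dark circular "position line" fiducials sit near the image corners,
# and each section carries a mild rigid + xy-coupled misalignment that the
# bilinear registration model can recover exactly.  Full ground truth
# (landmark centres, misalignment transforms, fascicle masks/contours, type
# labels, split/merge lineage) is returned alongside the pixel data.
# ---------------------------------------------------------------------------

FASCICLE_TYPES <- c("sensory", "motor", "mixed")

default_texture_params <- function() {
  list(
    background = c(0.87, 0.84, 0.88),
    granule_radius = c(1.0, 2.0),
    coverage = 0.72,
    means = c(sensory = 0.16, motor = 0.50, mixed = 0.42),
    mixed_dark_fraction = 0.20,
    intensity_sd = 0.03,
    noise_sd = 0.015,
    tints = list(sensory = c(0.80, 0.85, 1.30),
                 motor   = c(1.12, 0.90, 1.00),
                 mixed   = c(1.00, 0.92, 1.08))
  )
}

#' Configuration of a synthetic section stack
#'
#' @param n_sections number of serial sections (z step is 0.5 mm).
#' @param image_size raster size as (rows, cols) pixels.
#' @param n_fascicles_initial fascicle count in the first section.
#' @param split_merge_events list of events, each
#'   `list(section =, event = "split"|"merge", fascicle = id)`.  Section
#'   indices are 0-based and must be in `[1, n_sections - 1]`.  A merge joins
#'   the named fascicle with its generated mate (pair partner or split
#'   sibling); a split requires an elongated (pair-born or pre-planned)
#'   fascicle.
#' @param type_assignment named character vector mapping fascicle id to
#'   `"sensory"`, `"motor"` or `"mixed"`; unnamed ids cycle through the three
#'   types (children inherit / mix their parents').
#' @param landmark_diameter_px diameter of the position-line dots, 12..15.
#' @param misalignment_scale maximum per-section translation in px; rotation
#'   is up to 5 degrees and the xy-coupling coefficient scales with this too.
#'   0 gives identity transforms.
#' @param fascicle_radius_px base fascicle radius in px.
#' @param texture_params granular texture parameters; see
#'   `fascicle3d:::default_texture_params()`.
#' @param rng_seed integer seed; identical configs generate bit-identical
#'   stacks.
#' @return validated config object of class `stack_config`.
#' @export
stack_config <- function(n_sections = 16L,
                         image_size = c(768L, 1024L),
                         n_fascicles_initial = 3L,
                         split_merge_events = list(),
                         type_assignment = NULL,
                         landmark_diameter_px = 13L,
                         misalignment_scale = 4,
                         fascicle_radius_px = 22,
                         texture_params = list(),
                         rng_seed = 1L) {
  stopifnot(n_sections >= 1, n_fascicles_initial >= 1,
            length(image_size) == 2, all(image_size >= 64),
            misalignment_scale >= 0)
  if (landmark_diameter_px < 12 || landmark_diameter_px > 15)
    abort("fascicle3d_config_error",
          "landmark_diameter_px must lie in [12, 15]")
  for (ev in split_merge_events) {
    if (!is.list(ev) || !all(c("section", "event", "fascicle") %in% names(ev)))
      abort("fascicle3d_config_error",
            "events need fields section, event, fascicle")
    if (!ev$event %in% c("split", "merge"))
      abort("fascicle3d_config_error", "event must be 'split' or 'merge'")
    if (ev$section < 1 || ev$section >= n_sections)
      abort("fascicle3d_config_error",
            "event section index out of range [1, n_sections - 1]")
  }
  tp <- utils::modifyList(default_texture_params(), texture_params)
  structure(list(
    n_sections = as.integer(n_sections),
    image_size = as.integer(image_size),
    n_fascicles_initial = as.integer(n_fascicles_initial),
    split_merge_events = split_merge_events,
    type_assignment = type_assignment,
    landmark_diameter_px = landmark_diameter_px,
    misalignment_scale = misalignment_scale,
    fascicle_radius_px = fascicle_radius_px,
    texture_params = tp,
    rng_seed = as.integer(rng_seed)
  ), class = "stack_config")
}

# geometry helpers -----------------------------------------------------------

ELLIPSE_ELONGATION <- 1.7
PAIR_GAP <- 4          # px between paired circles
POLY_N <- 64           # vertices per ground-truth contour

ellipse_axes <- function(r) {
  a <- r * sqrt(2 * ELLIPSE_ELONGATION)
  b <- r * sqrt(2 / ELLIPSE_ELONGATION)
  c(a = a, b = b)
}

shape_inside <- function(sh, qr, qc) {
  dr <- qr - sh$center[1]; dc <- qc - sh$center[2]
  if (sh$shape == "circle") {
    dr * dr + dc * dc <= sh$r^2
  } else {
    u <- dr * sh$ax[1] + dc * sh$ax[2]
    w <- -dr * sh$ax[2] + dc * sh$ax[1]
    (u / sh$a)^2 + (w / sh$b)^2 <= 1
  }
}

shape_polygon <- function(sh, n = POLY_N) {
  phi <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  if (sh$shape == "circle") {
    cbind(sh$center[1] + sh$r * cos(phi), sh$center[2] + sh$r * sin(phi))
  } else {
    u <- sh$a * cos(phi); w <- sh$b * sin(phi)
    cbind(sh$center[1] + u * sh$ax[1] - w * sh$ax[2],
          sh$center[2] + u * sh$ax[2] + w * sh$ax[1])
  }
}

shape_bound_radius <- function(sh) if (sh$shape == "circle") sh$r else sh$a

shape_area <- function(sh) {
  if (sh$shape == "circle") pi * sh$r^2 else pi * sh$a * sh$b
}

# lineage planning -----------------------------------------------------------

plan_lineage <- function(config) {
  n0 <- config$n_fascicles_initial
  events <- config$split_merge_events
  if (length(events) > 0) {
    ord <- order(vapply(events, function(e) e$section, numeric(1)))
    events <- events[ord]
  }
  type_of <- function(id, default) {
    ta <- config$type_assignment
    if (!is.null(ta) && as.character(id) %in% names(ta))
      ta[[as.character(id)]] else default
  }

  merge_targets <- vapply(Filter(function(e) e$event == "merge", events),
                          function(e) e$fascicle, numeric(1))
  split_targets <- vapply(Filter(function(e) e$event == "split", events),
                          function(e) e$fascicle, numeric(1))

  # initial geometry roles
  paired <- integer(0)      # merge mates among initial ids
  mate <- list()
  used <- rep(FALSE, n0)
  for (id in merge_targets[merge_targets <= n0]) {
    if (used[id])
      abort("fascicle3d_config_error", "fascicle takes part in two merges")
    used[id] <- TRUE
    free <- setdiff(which(!used), c(split_targets, merge_targets))
    if (length(free) == 0)
      abort("fascicle3d_config_error",
            "no free initial fascicle available as merge partner")
    j <- free[1]
    used[j] <- TRUE
    mate[[as.character(id)]] <- j
    mate[[as.character(j)]] <- id
    paired <- c(paired, id, j)
  }
  list(events = events, mate = mate, paired = paired,
       split_initial = split_targets[split_targets <= n0],
       type_of = type_of)
}

place_slots <- function(config, plan) {
  rows <- config$image_size[1]; cols <- config$image_size[2]
  n0 <- config$n_fascicles_initial
  r0 <- config$fascicle_radius_px
  lo <- 0.26; hi <- 0.74

  # one slot per initial id, merge pairs share a slot
  slot_ids <- list(); taken <- rep(FALSE, n0)
  for (id in seq_len(n0)) {
    if (taken[id]) next
    m <- plan$mate[[as.character(id)]]
    if (!is.null(m) && m <= n0) {
      slot_ids[[length(slot_ids) + 1]] <- c(id, m)
      taken[c(id, m)] <- TRUE
    } else {
      slot_ids[[length(slot_ids) + 1]] <- id
      taken[id] <- TRUE
    }
  }
  radii <- lapply(slot_ids, function(ids) {
    if (length(ids) == 2) {
      r <- r0 + runif(1, -1, 1)
      list(r = r, bound = 2 * r + PAIR_GAP / 2 + 2)
    } else if (ids %in% plan$split_initial) {
      r <- r0 + runif(1, -1, 1)
      list(r = r, bound = ellipse_axes(r)["a"] + 2)
    } else {
      list(r = r0 * runif(1, 0.8, 1.3), bound = NA)
    }
  })
  for (k in seq_along(radii))
    if (is.na(radii[[k]]$bound)) radii[[k]]$bound <- radii[[k]]$r + 2

  centers <- matrix(NA_real_, length(slot_ids), 2)
  for (k in seq_along(slot_ids)) {
    ok <- FALSE
    for (attempt in 1:400) {
      cand <- c(runif(1, lo * rows, hi * rows), runif(1, lo * cols, hi * cols))
      sep <- TRUE
      if (k > 1) {
        for (j in seq_len(k - 1)) {
          need <- radii[[k]]$bound + radii[[j]]$bound + 12
          if (sqrt(sum((cand - centers[j, ])^2)) < need) { sep <- FALSE; break }
        }
      }
      if (sep) { centers[k, ] <- cand; ok <- TRUE; break }
    }
    if (!ok)
      abort("fascicle3d_placement_error",
            "could not place fascicles without overlap after 400 attempts")
  }
  list(ids = slot_ids, radii = radii, centers = centers)
}

# build state of every fascicle instance per section
build_timeline <- function(config, plan, slots) {
  n0 <- config$n_fascicles_initial
  type_cycle <- FASCICLE_TYPES
  state <- list()
  for (k in seq_along(slots$ids)) {
    ids <- slots$ids[[k]]
    if (length(ids) == 2) {
      theta <- runif(1, 0, pi)
      ax <- c(cos(theta), sin(theta))
      r <- slots$radii[[k]]$r
      off <- (r + PAIR_GAP / 2) * ax
      for (s in 1:2) {
        id <- ids[s]
        state[[as.character(id)]] <- list(
          id = id, shape = "circle",
          center = slots$centers[k, ] + (if (s == 1) off else -off),
          r = r, ax = ax,
          type = plan$type_of(id, type_cycle[(id - 1) %% 3 + 1]),
          mate = plan$mate[[as.character(id)]], alive = TRUE)
      }
    } else if (ids %in% plan$split_initial) {
      theta <- runif(1, 0, pi)
      r <- slots$radii[[k]]$r
      axes <- ellipse_axes(r)
      state[[as.character(ids)]] <- list(
        id = ids, shape = "ellipse", center = slots$centers[k, ],
        r = r, a = axes[["a"]], b = axes[["b"]],
        ax = c(cos(theta), sin(theta)),
        type = plan$type_of(ids, type_cycle[(ids - 1) %% 3 + 1]),
        mate = NULL, alive = TRUE)
    } else {
      state[[as.character(ids)]] <- list(
        id = ids, shape = "circle", center = slots$centers[k, ],
        r = slots$radii[[k]]$r, ax = c(1, 0),
        type = plan$type_of(ids, type_cycle[(ids - 1) %% 3 + 1]),
        mate = NULL, alive = TRUE)
    }
  }

  next_id <- n0 + 1L
  per_section <- vector("list", config$n_sections)
  lineage <- data.frame(parent = integer(), child = integer(),
                        section = integer(), event = character())
  ev_queue <- plan$events
  for (s in 0:(config$n_sections - 1L)) {
    while (length(ev_queue) > 0 && ev_queue[[1]]$section == s) {
      ev <- ev_queue[[1]]; ev_queue <- ev_queue[-1]
      key <- as.character(ev$fascicle)
      if (is.null(state[[key]]) || !state[[key]]$alive)
        abort("fascicle3d_config_error",
              paste("event references fascicle", ev$fascicle,
                    "which is not alive at section", s))
      f <- state[[key]]
      if (ev$event == "merge") {
        if (is.null(f$mate))
          abort("fascicle3d_config_error",
                paste("fascicle", f$id, "has no adjacent mate to merge with"))
        g <- state[[as.character(f$mate)]]
        if (is.null(g) || !g$alive)
          abort("fascicle3d_config_error", "merge mate no longer alive")
        child <- next_id; next_id <- next_id + 1L
        ctype <- plan$type_of(child,
                              if (f$type == g$type) f$type else "mixed")
        axes <- ellipse_axes(f$r)
        state[[as.character(child)]] <- list(
          id = child, shape = "ellipse",
          center = (f$center + g$center) / 2,
          r = f$r, a = axes[["a"]], b = axes[["b"]], ax = f$ax,
          type = ctype, mate = NULL, alive = TRUE)
        state[[key]]$alive <- FALSE
        state[[as.character(g$id)]]$alive <- FALSE
        lineage <- rbind(lineage,
                         data.frame(parent = c(f$id, g$id), child = child,
                                    section = s, event = "merge"))
      } else {
        if (f$shape != "ellipse")
          abort("fascicle3d_config_error",
                paste("fascicle", f$id, "is circular and cannot split;",
                      "splits need a pair-born or pre-planned fascicle"))
        c1 <- next_id; c2 <- next_id + 1L; next_id <- next_id + 2L
        off <- (f$r + PAIR_GAP / 2) * f$ax
        for (ci in c(c1, c2)) {
          state[[as.character(ci)]] <- list(
            id = ci, shape = "circle",
            center = f$center + (if (ci == c1) off else -off),
            r = f$r, ax = f$ax,
            type = plan$type_of(ci, f$type),
            mate = if (ci == c1) c2 else c1, alive = TRUE)
        }
        state[[key]]$alive <- FALSE
        lineage <- rbind(lineage,
                         data.frame(parent = f$id, child = c(c1, c2),
                                    section = s, event = "split"))
      }
    }
    alive <- Filter(function(x) x$alive, state)
    if (length(alive) == 0)
      abort("fascicle3d_config_error", "fascicle count dropped to zero")
    per_section[[s + 1L]] <- alive
  }
  list(per_section = per_section, lineage = lineage,
       types = vapply(state, function(x) x$type, character(1)))
}

# misalignment ---------------------------------------------------------------

random_misalignment <- function(config) {
  rows <- config$image_size[1]; cols <- config$image_size[2]
  s <- config$misalignment_scale
  if (s == 0) return(bilinear_identity())
  theta <- runif(1, -5, 5) * pi / 180
  tr <- runif(2, -s, s)
  cpl <- runif(2, -1, 1) * s / (rows * cols)
  m <- c((rows - 1) / 2, (cols - 1) / 2)
  a <- c(m[1] + tr[1] - cos(theta) * m[1] + sin(theta) * m[2],
         cos(theta), -sin(theta), cpl[1])
  b <- c(m[2] + tr[2] - sin(theta) * m[1] - cos(theta) * m[2],
         sin(theta), cos(theta), cpl[2])
  bilinear_transform(a, b)
}

# least-squares bilinear fit of the inverse map on a grid of correspondences
fit_inverse_on_grid <- function(t, rows, cols, n = 6) {
  gr <- seq(0, rows - 1, length.out = n)
  gc <- seq(0, cols - 1, length.out = n)
  p <- as.matrix(expand.grid(row = gr, col = gc))
  q <- apply_bilinear(t, p)
  M <- cbind(1, q[, 1], q[, 2], q[, 1] * q[, 2])
  a <- qr.solve(M, p[, 1])
  b <- qr.solve(M, p[, 2])
  bilinear_transform(a, b)
}

# rendering ------------------------------------------------------------------

landmark_reference_positions <- function(config) {
  rows <- config$image_size[1]; cols <- config$image_size[2]
  base <- rbind(c(0.11, 0.11), c(0.11, 0.89), c(0.89, 0.89), c(0.89, 0.11))
  jit <- matrix(runif(8, -0.018, 0.018), 4, 2)
  sweep(base + jit, 2, c(rows - 1, cols - 1), `*`)
}

paint_disk <- function(img, center, radius, rgb, noise_sd) {
  rows <- dim(img)[1]; cols <- dim(img)[2]
  r0 <- max(0, floor(center[1] - radius - 1)); r1 <- min(rows - 1, ceiling(center[1] + radius + 1))
  c0 <- max(0, floor(center[2] - radius - 1)); c1 <- min(cols - 1, ceiling(center[2] + radius + 1))
  if (r1 < r0 || c1 < c0) return(img)
  rr <- r0:r1; cc <- c0:c1
  dr <- outer(rr - center[1], rep(1, length(cc)))
  dc <- outer(rep(1, length(rr)), cc - center[2])
  sel <- dr * dr + dc * dc <= radius^2
  n <- sum(sel)
  if (n == 0) return(img)
  scale <- 1 + rnorm(n, 0, noise_sd)
  for (ch in 1:3) {
    sub <- img[rr + 1, cc + 1, ch]
    sub[sel] <- pmin(pmax(rgb[ch] * scale, 0), 1)
    img[rr + 1, cc + 1, ch] <- sub
  }
  img
}

render_section <- function(config, instances, transform, inv_transform,
                           landmarks_aligned) {
  rows <- config$image_size[1]; cols <- config$image_size[2]
  tp <- config$texture_params
  img <- array(0, c(rows, cols, 3))
  for (ch in 1:3) img[, , ch] <- tp$background[ch]
  mask <- matrix(0L, rows, cols)

  PR <- matrix(rep(0:(rows - 1), cols), rows, cols)
  PC <- matrix(rep(0:(cols - 1), each = rows), rows, cols)
  QR <- transform$a[1] + transform$a[2] * PR + transform$a[3] * PC +
    transform$a[4] * PR * PC
  QC <- transform$b[1] + transform$b[2] * PR + transform$b[3] * PC +
    transform$b[4] * PR * PC

  for (f in instances) {
    bound <- shape_bound_radius(f) + 3
    corners <- rbind(f$center + c(-bound, -bound), f$center + c(-bound, bound),
                     f$center + c(bound, -bound), f$center + c(bound, bound))
    pc <- apply_bilinear(inv_transform, corners)
    r0 <- max(0, floor(min(pc[, 1])) - 6); r1 <- min(rows - 1, ceiling(max(pc[, 1])) + 6)
    c0 <- max(0, floor(min(pc[, 2])) - 6); c1 <- min(cols - 1, ceiling(max(pc[, 2])) + 6)
    if (r1 < r0 || c1 < c0) next
    ri <- (r0:r1) + 1L; ci <- (c0:c1) + 1L
    qr <- QR[ri, ci]; qc <- QC[ri, ci]
    sel <- shape_inside(f, qr, qc)
    if (!any(sel)) next
    msub <- mask[ri, ci]; msub[sel] <- f$id; mask[ri, ci] <- msub

    # granules in the aligned frame
    area <- shape_area(f)
    gmean_area <- pi * mean(tp$granule_radius)^2
    # Poisson-overlap correction: n disks of area a cover 1 - exp(-n a / A)
    # of the region, so invert to hit the configured coverage fraction
    n_gran <- max(3L, as.integer(round(area * (-log(1 - tp$coverage)) /
                                         gmean_area)))
    bb <- shape_bound_radius(f)
    cand_r <- runif(4 * n_gran, f$center[1] - bb, f$center[1] + bb)
    cand_c <- runif(4 * n_gran, f$center[2] - bb, f$center[2] + bb)
    keep <- shape_inside(f, cand_r, cand_c)
    gr_ <- head(cand_r[keep], n_gran); gc_ <- head(cand_c[keep], n_gran)
    ng <- length(gr_)
    grad <- runif(ng, tp$granule_radius[1], tp$granule_radius[2])
    dark <- if (f$type == "mixed") runif(ng) < tp$mixed_dark_fraction else rep(FALSE, ng)
    base_mean <- ifelse(dark, tp$means[["sensory"]], tp$means[[f$type]])
    gint <- pmax(0.02, base_mean + rnorm(ng, 0, tp$intensity_sd))
    tint_main <- tp$tints[[f$type]]
    tint_dark <- tp$tints[["sensory"]]

    sub <- lapply(1:3, function(ch) img[ri, ci, ch])
    qr_sel <- qr[sel]; qc_sel <- qc[sel]
    sel_idx <- which(sel)
    for (g in seq_len(ng)) {
      hit <- (qr_sel - gr_[g])^2 + (qc_sel - gc_[g])^2 <= grad[g]^2
      if (!any(hit)) next
      tint <- if (dark[g]) tint_dark else tint_main
      for (ch in 1:3)
        sub[[ch]][sel_idx[hit]] <- min(1, gint[g] * tint[ch])
    }
    for (ch in 1:3) img[ri, ci, ch] <- sub[[ch]]
  }

  # position-line dots, drawn as true disks at the warped centre
  lm_obs <- invert_bilinear_at(transform, landmarks_aligned)
  for (k in 1:4) {
    img <- paint_disk(img, lm_obs[k, ], config$landmark_diameter_px / 2,
                      c(0.10, 0.12, 0.45), 0.04)
  }

  noise <- array(rnorm(rows * cols * 3, 0, tp$noise_sd), c(rows, cols, 3))
  img <- pmin(pmax(img + noise, 0), 1)
  list(image = img, mask = mask, landmarks = lm_obs)
}

#' Generate a synthetic serial-section stack with ground truth
#'
#' @param config a [stack_config()].
#' @return list with `sections` (list of RGB arrays), `z_mm` (section
#'   positions, 0.5 mm apart) and `truth`, a `stack_truth` object holding
#'   per-section landmark centres, misalignment transforms (`to_reference`
#'   maps observed into the aligned frame; `from_reference` is its fitted
#'   inverse), fascicle id masks, polygonal contours (observed frame), type
#'   labels and the split/merge lineage table.
#' @export
generate_stack <- function(config) {
  stopifnot(inherits(config, "stack_config"))
  with_seed(config$rng_seed, {
    plan <- plan_lineage(config)
    rows <- config$image_size[1]; cols <- config$image_size[2]

    timeline <- NULL; lm_aligned <- NULL
    for (attempt in 1:100) {
      slots <- place_slots(config, plan)
      timeline <- build_timeline(config, plan, slots)
      lm_aligned <- landmark_reference_positions(config)
      clear <- TRUE
      for (secs in timeline$per_section) {
        for (f in secs) {
          d <- sqrt((lm_aligned[, 1] - f$center[1])^2 +
                      (lm_aligned[, 2] - f$center[2])^2)
          if (any(d < shape_bound_radius(f) +
                    config$landmark_diameter_px / 2 + 5)) clear <- FALSE
        }
      }
      if (clear) break
      if (attempt == 100)
        abort("fascicle3d_placement_error",
              "landmarks kept overlapping fascicles after 100 layouts")
    }

    transforms <- vector("list", config$n_sections)
    for (s in seq_len(config$n_sections)) {
      transforms[[s]] <- if (s == 1) bilinear_identity() else
        random_misalignment(config)
    }
    inv_transforms <- lapply(transforms, fit_inverse_on_grid, rows = rows,
                             cols = cols)

    sections <- vector("list", config$n_sections)
    masks <- vector("list", config$n_sections)
    contours <- vector("list", config$n_sections)
    lm_rows <- list()
    for (s in seq_len(config$n_sections)) {
      inst <- timeline$per_section[[s]]
      rend <- render_section(config, inst, transforms[[s]],
                             inv_transforms[[s]], lm_aligned)
      sections[[s]] <- rend$image
      masks[[s]] <- rend$mask
      polys <- lapply(inst, function(f)
        invert_bilinear_at(transforms[[s]], shape_polygon(f)))
      names(polys) <- vapply(inst, function(f) as.character(f$id), character(1))
      contours[[s]] <- polys
      lm_rows[[s]] <- data.frame(section = s - 1L,
                                 label = c("S_a", "S_b", "S_c", "S_d"),
                                 row = rend$landmarks[, 1],
                                 col = rend$landmarks[, 2])
    }

    truth <- structure(list(
      landmarks = do.call(rbind, lm_rows),
      landmarks_aligned = lm_aligned,
      transforms = transforms,
      inv_transforms = inv_transforms,
      masks = masks,
      contours = contours,
      types = timeline$types,
      lineage = timeline$lineage,
      config = config
    ), class = "stack_truth")

    list(sections = sections,
         z_mm = (seq_len(config$n_sections) - 1) * 0.5,
         truth = truth)
  })
}

#' Per-section fascicle counts of a ground truth object
#' @param truth `stack_truth` from [generate_stack()].
#' @return integer vector, one count per section.
#' @export
truth_counts <- function(truth) {
  vapply(truth$contours, length, integer(1))
}

# template windows -----------------------------------------------------------

draw_window_disk <- function(win, center, radius, intensity) {
  rr <- matrix(rep(0:14, 15), 15, 15)
  cc <- matrix(rep(0:14, each = 15), 15, 15)
  sel <- (rr - center[1])^2 + (cc - center[2])^2 <= radius^2
  tint <- c(0.85, 0.9, 2.6)
  for (ch in 1:3) {
    w <- win[, , ch]
    w[sel] <- pmin(1, intensity * tint[ch]) + rnorm(sum(sel), 0, 0.02)
    win[, , ch] <- w
  }
  win
}

new_window <- function() {
  win <- array(0, c(15, 15, 3))
  bg <- c(0.87, 0.84, 0.88)
  for (ch in 1:3) win[, , ch] <- bg[ch] + rnorm(225, 0, 0.02)
  win
}

#' Generate labelled 15 x 15 template windows
#'
#' Positives contain a centred dark circle-like blob whose edge lies in the
#' ring band of [ring_template()]; negatives are granular texture, off-centre,
#' partial, under- and over-sized blobs, and blob pairs.
#'
#' @param n_positive,n_negative counts per class (each >= 1).
#' @param seed integer seed.
#' @return a `template_set`: list with `windows` (list of 15 x 15 x 3
#'   arrays), `labels` (`"circle"` / `"noncircle"`), `y` (+1 / -1) and
#'   `features` (n x 225 matrix from [window_features()]).
#' @export
generate_template_windows <- function(n_positive, n_negative, seed = 1L) {
  stopifnot(n_positive >= 1, n_negative >= 1)
  with_seed(seed, {
    wins <- vector("list", n_positive + n_negative)
    labels <- character(n_positive + n_negative)
    for (i in seq_len(n_positive)) {
      win <- new_window()
      ctr <- c(7, 7) + runif(2, -0.3, 0.3)
      wins[[i]] <- draw_window_disk(win, ctr, runif(1, 6.0, 7.2),
                                    runif(1, 0.10, 0.18))
      labels[i] <- "circle"
    }
    kinds <- rep_len(1:6, n_negative)
    for (j in seq_len(n_negative)) {
      i <- n_positive + j
      win <- new_window()
      win <- switch(kinds[j],
        { # granular texture
          for (g in 1:10) {
            win <- draw_window_disk(win, runif(2, 0, 14), runif(1, 0.8, 1.8),
                                    runif(1, 0.15, 0.5))
          }
          win
        },
        draw_window_disk(win, c(7, 7) + sample(c(-1, 1), 2, TRUE) *
                           runif(2, 2.5, 4.5), runif(1, 6.0, 7.2),
                         runif(1, 0.10, 0.18)),          # off-centre
        draw_window_disk(win, c(runif(1, -2, 2), runif(1, 12, 16)),
                         runif(1, 6.0, 7.2), runif(1, 0.10, 0.18)), # partial
        draw_window_disk(win, c(7, 7) + runif(2, -0.5, 0.5),
                         runif(1, 2.5, 4.2), runif(1, 0.10, 0.18)), # small
        draw_window_disk(win, c(7, 7) + runif(2, -0.5, 0.5),
                         runif(1, 8.8, 10.5), runif(1, 0.10, 0.18)), # large
        { # two small blobs
          win <- draw_window_disk(win, c(4, 4) + runif(2, -1, 1),
                                  runif(1, 2.5, 3.5), runif(1, 0.1, 0.2))
          draw_window_disk(win, c(10, 10) + runif(2, -1, 1),
                           runif(1, 2.5, 3.5), runif(1, 0.1, 0.2))
        })
      wins[[i]] <- pmin(pmax(win, 0), 1)
      labels[i] <- "noncircle"
    }
    structure(list(
      windows = wins,
      labels = labels,
      y = ifelse(labels == "circle", 1, -1),
      features = window_features(wins)
    ), class = "template_set")
  })
}

#' Flatten windows into LS-SVM feature rows
#'
#' Each 15 x 15 window is converted to grayscale, flattened column-major and
#' min-max normalized to [0, 1] (constant windows map to all zeros).
#'
#' @param windows list of 15 x 15 x 3 arrays (or matrices).
#' @return n x 225 numeric matrix.
#' @export
window_features <- function(windows) {
  t(vapply(windows, function(w) {
    g <- as.vector(rgb_to_gray(w))
    rng <- range(g)
    if (rng[2] - rng[1] < 1e-12) return(rep(0, length(g)))
    (g - rng[1]) / (rng[2] - rng[1])
  }, numeric(225)))
}

# stack / ground-truth disk interfaces ---------------------------------------

#' Write a stack to a directory of ASCII PPM files
#' @param stack result of [generate_stack()] (or any list with `sections`).
#' @param dir output directory (created).
#' @return invisible vector of file paths.
#' @export
write_stack <- function(stack, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(length(stack$sections))
  for (s in seq_along(stack$sections)) {
    paths[s] <- file.path(dir, sprintf("section_%03d.ppm", s - 1L))
    write_pnm(stack$sections[[s]], paths[s])
  }
  invisible(paths)
}

#' Read a directory of ASCII PPM sections (sorted by filename)
#' @param dir directory produced by [write_stack()].
#' @return list of RGB arrays.
#' @export
read_stack <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.ppm$", full.names = TRUE))
  if (length(files) == 0)
    abort("fascicle3d_io_error", paste("no .ppm sections found in", dir))
  lapply(files, read_pnm)
}

#' Write ground truth (landmarks CSV, transforms CSV, lineage/types JSON,
#' per-section label-mask PGMs)
#' @param truth `stack_truth` object.
#' @param dir output directory.
#' @export
write_ground_truth <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(truth$landmarks, file.path(dir, "landmarks.csv"),
            row.names = FALSE)
  tr <- do.call(rbind, lapply(seq_along(truth$transforms), function(s) {
    t <- truth$transforms[[s]]
    data.frame(section = s - 1L,
               a0 = t$a[1], a1 = t$a[2], a2 = t$a[3], a3 = t$a[4],
               b0 = t$b[1], b1 = t$b[2], b2 = t$b[3], b3 = t$b[4])
  }))
  write.csv(tr, file.path(dir, "transforms.csv"), row.names = FALSE)
  jsonlite::write_json(list(types = as.list(truth$types),
                            lineage = truth$lineage),
                       file.path(dir, "lineage.json"), auto_unbox = TRUE,
                       digits = NA)
  for (s in seq_along(truth$masks))
    write_pnm(truth$masks[[s]],
              file.path(dir, sprintf("mask_%03d.pgm", s - 1L)))
  invisible(dir)
}
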