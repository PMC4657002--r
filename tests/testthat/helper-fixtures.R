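# Shared fixtures, memoised so each expensive object is generated once per
# test run.  All fixtures are fully synthetic with fixed seeds.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# 5-section misaligned stack without events (detection / registration tests)
fixture_stack5 <- function() memo("stack5", {
  generate_stack(stack_config(
    n_sections = 5, image_size = c(240, 320), n_fascicles_initial = 3,
    misalignment_scale = 4, rng_seed = 7))
})

# single aligned section with one fascicle of each type (segmentation/typing)
fixture_section <- function() memo("section", {
  generate_stack(stack_config(
    n_sections = 1, image_size = c(240, 320), n_fascicles_initial = 3,
    misalignment_scale = 0, rng_seed = 7))
})

# template windows and a trained detector
fixture_windows <- function() memo("windows", generate_template_windows(120, 120, seed = 3))
fixture_detector <- function() memo("detector", train_detector(fixture_windows()))

# the canonical end-to-end world: 16 sections, 3 initial fascicles, one merge
# (sensory + motor -> mixed) and one split (sensory -> two sensory)
canonical_config <- function(seed = 1L) {
  stack_config(
    n_sections = 16, image_size = c(240, 320), n_fascicles_initial = 3,
    split_merge_events = list(list(section = 5, event = "merge", fascicle = 1),
                              list(section = 10, event = "split", fascicle = 3)),
    type_assignment = c("1" = "sensory", "2" = "motor", "3" = "sensory"),
    misalignment_scale = 4, rng_seed = seed)
}
fixture_canonical <- function() memo("canonical", generate_stack(canonical_config()))

# granular disk, radius 60, for the snake-mode comparison
fixture_disk <- function() memo("disk", {
  set.seed(1)
  img <- array(0, c(200, 200, 3))
  for (ch in 1:3) img[, , ch] <- 0.85 + rnorm(40000, 0, 0.015)
  rr <- matrix(rep(0:199, 200), 200, 200)
  cc <- matrix(rep(0:199, each = 200), 200, 200)
  ng <- round(pi * 60^2 * (-log(1 - 0.72)) / (pi * 1.5^2))
  gr_ <- runif(3 * ng, 40, 160); gc_ <- runif(3 * ng, 40, 160)
  keep <- (gr_ - 100)^2 + (gc_ - 100)^2 <= 60^2
  gr_ <- head(gr_[keep], ng); gc_ <- head(gc_[keep], ng)
  for (g in seq_along(gr_)) {
    hit <- (rr - gr_[g])^2 + (cc - gc_[g])^2 <= runif(1, 1, 2)^2
    for (ch in 1:3) { m <- img[, , ch]; m[hit] <- 0.16; img[, , ch] <- m }
  }
  img
})

# --- metric helpers ---------------------------------------------------------

adjusted_rand_index <- function(a, b) {
  tab <- table(a, b); n <- sum(tab)
  si <- sum(choose(rowSums(tab), 2)); sj <- sum(choose(colSums(tab), 2))
  sij <- sum(choose(tab, 2)); e <- si * sj / choose(n, 2)
  (sij - e) / ((si + sj) / 2 - e)
}

# mean distance from contour vertices to a densified reference polygon
mean_boundary_dist <- function(verts, ref_poly, dense = 600) {
  ref <- fascicle3d:::resample_closed(ref_poly, dense)
  d <- sqrt(outer(verts[, 1], ref[, 1], "-")^2 +
              outer(verts[, 2], ref[, 2], "-")^2)
  mean(apply(d, 1, min))
}

# symmetric curve Hausdorff distance between closed polygons
hausdorff_curves <- function(a, b, dense = 600) {
  ad <- fascicle3d:::resample_closed(a, dense)
  bd <- fascicle3d:::resample_closed(b, dense)
  h1 <- max(apply(sqrt(outer(a[, 1], bd[, 1], "-")^2 +
                         outer(a[, 2], bd[, 2], "-")^2), 1, min))
  h2 <- max(apply(sqrt(outer(b[, 1], ad[, 1], "-")^2 +
                         outer(b[, 2], ad[, 2], "-")^2), 1, min))
  max(h1, h2)
}

# truth contours of section s (1-based) mapped into the aligned frame
truth_contours_aligned <- function(stk, s) {
  lapply(stk$truth$contours[[s]], function(p)
    apply_bilinear(stk$truth$transforms[[s]], p))
}

mask_jaccard <- function(a, b) sum(a & b) / sum(a | b)

# straight-loop GVF oracle (independent of the package implementation)
gvf_oracle <- function(em, mu, n_iter, dt) {
  nr <- nrow(em); nc <- ncol(em)
  at <- function(m, i, j) m[min(max(i, 1), nr), min(max(j, 1), nc)]
  gr <- matrix(0, nr, nc); gc <- matrix(0, nr, nc)
  for (i in 1:nr) for (j in 1:nc) {
    gr[i, j] <- (at(em, i + 1, j) - at(em, i - 1, j)) / 2
    gc[i, j] <- (at(em, i, j + 1) - at(em, i, j - 1)) / 2
  }
  b <- gr^2 + gc^2
  u <- gr; v <- gc
  for (it in seq_len(n_iter)) {
    lu <- matrix(0, nr, nc); lv <- matrix(0, nr, nc)
    for (i in 1:nr) for (j in 1:nc) {
      lu[i, j] <- at(u, i + 1, j) + at(u, i - 1, j) + at(u, i, j + 1) +
        at(u, i, j - 1) - 4 * u[i, j]
      lv[i, j] <- at(v, i + 1, j) + at(v, i - 1, j) + at(v, i, j + 1) +
        at(v, i, j - 1) - 4 * v[i, j]
    }
    u <- u + dt * (mu * lu - b * (u - gr))
    v <- v + dt * (mu * lv - b * (v - gc))
  }
  list(u = u, v = v)
}

# plain Lloyd k-means from a fixed set of initial centres (oracle)
lloyd_kmeans <- function(x, centers, max_iter = 100) {
  for (it in seq_len(max_iter)) {
    d2 <- outer(rowSums(x^2), rowSums(centers^2), `+`) - 2 * tcrossprod(x, centers)
    assign <- max.col(-d2, ties.method = "first")
    new_centers <- centers
    for (k in seq_len(nrow(centers)))
      if (any(assign == k))
        new_centers[k, ] <- colMeans(x[assign == k, , drop = FALSE])
    if (max(abs(new_centers - centers)) < 1e-12) { centers <- new_centers; break }
    centers <- new_centers
  }
  d2 <- outer(rowSums(x^2), rowSums(centers^2), `+`) - 2 * tcrossprod(x, centers)
  list(centers = centers, assign = max.col(-d2, ties.method = "first"))
}
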