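test_that("preprocessing isolates fascicle texture and drops landmark dots", {
  stk <- fixture_section()
  img <- stk$sections[[1]]
  fg <- preprocess_section(img)
  truth <- stk$truth$masks[[1]] > 0
  expect_gte(mask_jaccard(fg, truth), 0.8)

  lm <- stk$truth$landmarks[stk$truth$landmarks$section == 0, c("row", "col")]
  expect_false(any(fg[cbind(round(lm$row) + 1, round(lm$col) + 1)]))

  expect_error(preprocess_section(array(1, c(60, 60, 3))),
               class = "fascicle3d_empty_section")
})

test_that("dynamic clustering finds the fascicle count without being told k", {
  # single tight blob -> one cluster at its mean
  set.seed(4)
  pts <- cbind(rnorm(400, 50, 4), rnorm(400, 60, 4))
  cl <- cluster_fascicle_pixels(pts)
  expect_equal(cl$k, 1L)
  expect_lt(max(abs(cl$centers[1, ] - colMeans(pts))), 1)
  expect_equal(cl$centers[1, ], colMeans(pts[cl$assignment == 1, ]),
               ignore_attr = TRUE)

  # two blobs 200 px apart -> two clusters
  pts2 <- rbind(pts, cbind(rnorm(400, 50, 4), rnorm(400, 260, 4)))
  cl2 <- cluster_fascicle_pixels(pts2)
  expect_equal(cl2$k, 2L)

  # deterministic
  expect_identical(cluster_fascicle_pixels(pts2), cluster_fascicle_pixels(pts2))

  # real section: k matches the generated fascicle count
  stk <- fixture_section()
  fg <- preprocess_section(stk$sections[[1]])
  cl3 <- cluster_fascicle_pixels(mask_points(fg))
  expect_equal(cl3$k, length(stk$truth$contours[[1]]))
})

test_that("GVF matches a straight-loop oracle and respects its contracts", {
  # constant edge map -> zero field
  f0 <- compute_gvf(matrix(0.5, 12, 12), mu = 0.2, n_iter = 10)
  expect_equal(max(abs(f0$u)), 0)
  expect_equal(max(abs(f0$v)), 0)

  # stability bound enforcement
  expect_error(compute_gvf(matrix(0, 5, 5), mu = 0.5, n_iter = 1, dt = 1),
               class = "fascicle3d_config_error")

  # 9 x 9 oracle equivalence to 1e-12
  set.seed(2)
  em <- matrix(runif(81), 9, 9)
  f <- compute_gvf(em, mu = 0.2, n_iter = 5, dt = 1)
  o <- gvf_oracle(em, 0.2, 5, 1)
  expect_lt(max(abs(f$u - o$u), abs(f$v - o$v)), 1e-12)

  # capture range: outside a disk the field points toward the boundary
  m <- matrix(0, 80, 80)
  rr <- matrix(rep(0:79, 80), 80, 80); cc <- matrix(rep(0:79, each = 80), 80, 80)
  m[(rr - 40)^2 + (cc - 40)^2 <= 20^2] <- 1
  soft <- blur_gaussian(m, 1.5)
  g <- image_gradient(soft)
  em2 <- sqrt(g$gr^2 + g$gc^2)
  fld <- compute_gvf(em2, mu = 0.2, n_iter = 300)
  for (ang in seq(0, 2 * pi, length.out = 9)[-9]) {
    p <- c(40 + 30 * cos(ang), 40 + 30 * sin(ang))   # 10 px outside
    Fv <- c(bilinear_sample(fld$u, p[1], p[2], 0),
            bilinear_sample(fld$v, p[1], p[2], 0))
    inward <- c(40, 40) - p
    expect_gt(sum(Fv * inward), 0)
  }
})

test_that("a snake with no forces on a vanishing field is a fixed point", {
  field <- structure(list(u = matrix(0, 100, 100), v = matrix(0, 100, 100),
                          mu = 0.2, dt = 1, iterations_run = 0L),
                     class = "gvf_field")
  init <- circle_contour(c(50, 50), 20, 60)
  sn <- evolve_snake(init, field, alpha = 0, beta = 0, n_vertices = 60,
                     max_iter = 5)
  expect_true(sn$converged)
  expect_equal(sn$vertices, init, tolerance = 1e-9)
})

test_that("snake energy is non-increasing while enveloping the disk", {
  m <- matrix(0, 140, 140)
  rr <- matrix(rep(0:139, 140), 140, 140)
  cc <- matrix(rep(0:139, each = 140), 140, 140)
  m[(rr - 70)^2 + (cc - 70)^2 <= 45^2] <- 1
  soft <- blur_gaussian(m, 2)
  g <- image_gradient(soft)
  em <- sqrt(g$gr^2 + g$gc^2); em <- em / max(em)
  field <- compute_gvf(em, 0.2, 200)
  x <- circle_contour(c(70, 70), 60, 80)   # enclosing init
  Minv <- fascicle3d:::snake_internal_matrix(80, 0.1, 0.5, 1)
  energy <- function(x) {
    n <- nrow(x)
    d1 <- x[c(2:n, 1), ] - x
    d2 <- x[c(2:n, 1), ] - 2 * x + x[c(n, 1:(n - 1)), ]
    sum(0.1 * rowSums(d1^2) + 0.5 * rowSums(d2^2)) -
      sum(bilinear_sample(em, x[, 1], x[, 2], 0))
  }
  es <- numeric(50)
  for (it in 1:50) {
    Fv <- cbind(bilinear_sample(field$u, x[, 1], x[, 2], 0),
                bilinear_sample(field$v, x[, 1], x[, 2], 0))
    nrm <- fascicle3d:::contour_normals(x)
    Fv <- nrm * rowSums(Fv * nrm)
    x <- fascicle3d:::resample_closed(Minv %*% (x + Fv), 80)
    es[it] <- energy(x)
  }
  expect_true(all(diff(es) <= 1e-6))
})

test_that("contour extraction yields one accurate, disjoint polygon per cluster", {
  stk <- fixture_section()
  img <- stk$sections[[1]]
  fg <- preprocess_section(img)
  pts <- mask_points(fg)
  cl <- cluster_fascicle_pixels(pts)
  sn <- extract_fascicle_contours(img, cl, pts)
  expect_length(sn, cl$k)
  expect_true(all(!vapply(sn, is.null, logical(1))))

  errs <- vapply(sn, function(s)
    min(vapply(stk$truth$contours[[1]], function(tp)
      mean_boundary_dist(s$vertices, tp), numeric(1))), numeric(1))
  expect_lt(mean(errs), 2)

  # pairwise disjoint simple polygons
  masks <- lapply(sn, function(s) rasterize_polygon(s$vertices, 240, 320))
  for (i in seq_len(length(masks) - 1))
    for (j in seq(i + 1, length(masks)))
      expect_equal(sum(masks[[i]] & masks[[j]]), 0)
})

test_that("near-touching merge parents stay disjoint and clustering tracks the merge", {
  cfg <- stack_config(n_sections = 3, image_size = c(240, 320),
                      n_fascicles_initial = 2, split_merge_events =
                        list(list(section = 1, event = "merge", fascicle = 1)),
                      misalignment_scale = 0, rng_seed = 5)
  stk <- generate_stack(cfg)
  ks <- integer(2)
  for (s in 1:2) {
    fg <- preprocess_section(stk$sections[[s]])
    pts <- mask_points(fg)
    cl <- cluster_fascicle_pixels(pts)
    ks[s] <- cl$k
    sn <- extract_fascicle_contours(stk$sections[[s]], cl, pts)
    masks <- lapply(sn, function(x) rasterize_polygon(x$vertices, 240, 320))
    if (length(masks) == 2)
      expect_equal(sum(masks[[1]] & masks[[2]]), 0)
  }
  expect_equal(ks, c(2L, 1L))
})
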