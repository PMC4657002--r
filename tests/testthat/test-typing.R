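test_that("neighbourhood spec and border contracts are enforced", {
  expect_error(neighborhood_spec(4), class = "fascicle3d_config_error")
  sp <- neighborhood_spec(11)
  expect_equal(sp$side, 23L)
  expect_equal(sp$directions, c(0L, 45L, 90L, 135L))
  img <- array(0.5, c(30, 30, 3))
  expect_error(directional_gradient_curves(img, c(3, 15), neighborhood_spec(5)),
               class = "fascicle3d_border_error")
})

test_that("gradient curves have the contracted lengths for every r", {
  img <- array(runif(120 * 120 * 3), c(120, 120, 3))
  for (r in c(5, 8, 11, 15)) {
    gc <- directional_gradient_curves(img, c(60, 60), neighborhood_spec(r))
    for (ch in gc$channels) for (d in ch) {
      expect_length(d$first, 2 * r)
      expect_length(d$second, 2 * r - 1)
    }
  }
  # constant image -> identically zero curves
  gc0 <- directional_gradient_curves(array(0.7, c(40, 40, 3)), c(20, 20),
                                     neighborhood_spec(8))
  expect_true(all(vapply(gc0$channels, function(ch)
    all(vapply(ch, function(d) all(d$first == 0) && all(d$second == 0),
               logical(1))), logical(1))))
})

test_that("an alternating 0/255 profile gives +-255 and -+510 differences", {
  img <- array(0, c(40, 40, 3))
  img[20 + 1, seq(1, 40, 2), ] <- 255   # alternate along the row (0 deg)
  gc <- directional_gradient_curves(img, c(20, 20), neighborhood_spec(5))
  first <- gc$channels[[1]][["0"]]$first
  expect_setequal(unique(abs(first)), 255)
  expect_true(all(abs(diff(sign(first))) == 2))  # alternating signs
  second <- gc$channels[[1]][["0"]]$second
  expect_setequal(unique(abs(second)), 510)
})

test_that("curve descriptors follow the documented conventions", {
  expect_equal(unname(curve_descriptors(rep(0, 10))), c(0, 0, 0))
  expect_equal(unname(curve_descriptors(c(0, 5, 0, 3, 0, 5, 0))), c(5, 5, 2))
  expect_equal(unname(curve_descriptors(c(0, 0, 7, 0, 0)))[3], 0)  # single peak
  # plateau credited to its leftmost index
  expect_equal(unname(curve_descriptors(c(0, 4, 4, 0, 2, 0))),
               c(4, 4, 3))  # peaks at 1 and 4 -> interval 3
})

test_that("feature vectors are 72-dimensional for every r and sampling is reproducible", {
  stk <- fixture_section()
  img <- stk$sections[[1]]
  for (r in c(5, 8, 11, 15)) {
    v <- pixel_feature_vector(img, c(120, 160), neighborhood_spec(r))
    expect_length(v, 72)
  }
  fm1 <- build_feature_matrix(img, 200, neighborhood_spec(11), seed = 3)
  fm2 <- build_feature_matrix(img, 200, neighborhood_spec(11), seed = 3)
  expect_identical(fm1, fm2)
  expect_equal(dim(fm1$features), c(200L, 72L))

  # constant image -> all amplitude columns zero
  fm0 <- build_feature_matrix(array(0.4, c(60, 60, 3)), 20,
                              neighborhood_spec(5), seed = 1)
  expect_true(all(fm0$features[, grep("max|second", colnames(fm0$features))] == 0))

  expect_error(build_feature_matrix(img, 1e7, neighborhood_spec(11), seed = 1),
               class = "fascicle3d_config_error")
})

test_that("the vectorized feature matrix equals the per-pixel reference", {
  stk <- fixture_section()
  img <- stk$sections[[1]]
  fm <- build_feature_matrix(img, 25, neighborhood_spec(7), seed = 5)
  for (i in c(1, 7, 25)) {
    ref <- pixel_feature_vector(img, fm$coords[i, ], neighborhood_spec(7))
    expect_equal(unname(fm$features[i, ]), unname(ref), tolerance = 1e-12)
  }
})

test_that("rough K-means with eps = 0 reduces exactly to classical K-means", {
  set.seed(6)
  x <- rbind(matrix(rnorm(60, 0), 30), matrix(rnorm(60, 4), 30),
             matrix(rnorm(60, 9), 30))
  cl <- rough_kmeans(x, k = 3, eps = 0, seed = 12, scale = FALSE)
  expect_true(all(!is.na(cl$lower)))
  # same k-means++ initial centres, plain Lloyd oracle
  init <- fascicle3d:::with_seed(12, {
    ux <- unique(x)
    cen <- ux[sample(nrow(ux), 1), , drop = FALSE]
    while (nrow(cen) < 3) {
      d2 <- apply(outer(rowSums(ux^2), rowSums(cen^2), `+`) -
                    2 * tcrossprod(ux, cen), 1, min)
      p <- pmax(d2, 0) / sum(pmax(d2, 0))
      cen <- rbind(cen, ux[sample(nrow(ux), 1, prob = p), ])
    }
    cen
  })
  oracle <- lloyd_kmeans(x, init)
  expect_equal(unname(cl$centers), unname(oracle$centers), tolerance = 1e-9)
  expect_equal(cl$lower, oracle$assign)
})

test_that("the 1-D six-point example recovers the brute-force optimum", {
  x <- matrix(c(0, 1, 2, 10, 11, 12), ncol = 1)
  # brute force over all 2-partitions
  best <- NULL; best_ss <- Inf
  for (bits in 1:(2^6 - 2)) {
    part <- as.logical(bitwAnd(bits, 2^(0:5)))
    if (!any(part) || all(part)) next
    ss <- sum((x[part] - mean(x[part]))^2) + sum((x[!part] - mean(x[!part]))^2)
    if (ss < best_ss) { best_ss <- ss; best <- part }
  }
  expect_equal(sort(x[best]), c(0, 1, 2))  # the optimum splits the two triplets
  cl <- rough_kmeans(x, k = 2, eps = 0, seed = 3, scale = FALSE)
  expect_setequal(x[cl$lower == cl$lower[1]], c(0, 1, 2))
  expect_setequal(sort(as.vector(cl$centers)), c(1, 11))
})

test_that("rough memberships keep lower inside upper with valid weights", {
  set.seed(7)
  x <- matrix(rnorm(200), 100, 2)
  expect_error(rough_kmeans(x, k = 2, w_lower = 0.5, w_upper = 0.3),
               class = "fascicle3d_config_error")
  cl <- rough_kmeans(x, k = 3, eps = 1.3, seed = 2, scale = FALSE)
  for (c. in 1:3) {
    lo <- which(!is.na(cl$lower) & cl$lower == c.)
    expect_true(all(lo %in% cl$upper[[c.]]))
  }
  # every point: exactly one lower set, or >= 2 upper sets
  n_upper <- rowSums(vapply(cl$upper, function(u) seq_len(100) %in% u,
                            logical(100)))
  expect_true(all(ifelse(is.na(cl$lower), n_upper >= 2, n_upper >= 1)))
  # auto eps lands at a sane ratio threshold
  cla <- rough_kmeans(x, k = 3, eps = "auto", seed = 2, scale = FALSE)
  expect_gte(cla$eps, 1)
})

test_that("fascicle labelling votes, breaks ties to mixed, flags empty contours", {
  stk <- fixture_section()
  img <- stk$sections[[1]]
  fg <- preprocess_section(img)
  fm <- build_feature_matrix(img, 1500, neighborhood_spec(11), seed = 2,
                             mask = fg)
  cl <- rough_kmeans(fm$features, k = 3, seed = 2, nstart = 6)
  res <- label_fascicles(stk$truth$contours[[1]], cl, fm$coords, img)
  truth <- stk$truth$types[names(stk$truth$contours[[1]])]
  expect_equal(unname(res$types), unname(truth))
  expect_setequal(res$cluster_types, c("sensory", "motor", "mixed"))

  # a contour far from any sampled pixel is unknown, with a warning
  far <- circle_contour(c(5, 5), 3, 12)
  expect_warning(res2 <- label_fascicles(list(far), cl, fm$coords, img),
                 "unknown")
  expect_equal(res2$types, "unknown")
})

test_that("an exact vote tie is labelled mixed by convention", {
  # hand-built clustering: one dark and one light pixel inside the contour,
  # one vote each for the sensory and motor clusters
  img <- array(0.5, c(40, 40, 3))
  img[21, 21, ] <- 0.1   # pixel (20, 20): dark
  img[21, 25, ] <- 0.9   # pixel (20, 24): light
  img[31, 31, ] <- 0.5
  coords <- rbind(c(20, 20), c(20, 24), c(30, 30))
  cl <- structure(list(k = 3L, centers = diag(3), lower = c(1L, 2L, 3L),
                       upper = list(1L, 2L, 3L), eps = 0,
                       w_lower = 0.7, w_upper = 0.3, iterations = 1L),
                  class = "rough_clustering")
  contour <- circle_contour(c(20, 22), 5, 24)
  res <- label_fascicles(list(contour), cl, coords, img)
  expect_equal(res$types, "mixed")
})
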