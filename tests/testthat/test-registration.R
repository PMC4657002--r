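ref_square <- function() {
  m <- rbind(c(10, 10), c(10, 80), c(70, 80), c(70, 10))
  rownames(m) <- c("S_a", "S_b", "S_c", "S_d")
  m
}

test_that("fit_bilinear recovers identity, translation and random transforms", {
  ref <- ref_square()
  expect_equal(fit_bilinear(ref, ref)$a, c(0, 1, 0, 0))
  expect_equal(fit_bilinear(ref, ref)$b, c(0, 0, 1, 0))

  # moving = reference - (5, 3) forces the pure-translation coefficients
  t <- fit_bilinear(ref, sweep(ref, 2, c(5, 3)))
  expect_equal(t$a, c(5, 1, 0, 0), tolerance = 1e-12)
  expect_equal(t$b, c(3, 0, 1, 0), tolerance = 1e-12)

  set.seed(8)
  for (rep in 1:5) {
    tt <- bilinear_transform(c(runif(1, -5, 5), 1 + runif(1, -0.05, 0.05),
                               runif(1, -0.05, 0.05), runif(1, -1e-4, 1e-4)),
                             c(runif(1, -5, 5), runif(1, -0.05, 0.05),
                               1 + runif(1, -0.05, 0.05), runif(1, -1e-4, 1e-4)))
    fwd <- apply_bilinear(tt, ref)
    fit <- fit_bilinear(fwd, ref)
    expect_lt(max(abs(c(fit$a - tt$a, fit$b - tt$b))), 1e-9)
    expect_lt(max(abs(apply_bilinear(fit, ref) - fwd)), 1e-9)
  }
})

test_that("degenerate control points raise SingularGeometryError", {
  ref <- ref_square()
  collinear <- cbind(c(1, 2, 3, 4), c(2, 4, 6, 8))
  expect_error(fit_bilinear(ref, collinear),
               class = "fascicle3d_singular_geometry")
})

test_that("warp_section is exact for identity and integer translations", {
  stk <- fixture_section()
  img <- stk$sections[[1]]
  expect_equal(warp_section(img, bilinear_identity()), img, tolerance = 1e-12)

  t <- bilinear_transform(c(4, 1, 0, 0), c(7, 0, 1, 0))  # out(p) = img(p + (4,7))
  out <- warp_section(img, t)
  rows <- dim(img)[1]; cols <- dim(img)[2]
  expect_equal(out[1:(rows - 4), 1:(cols - 7), ],
               img[5:rows, 8:cols, ], tolerance = 1e-12)
  # interpolation conserves the intensity range
  expect_gte(min(out), min(img))
  expect_lte(max(out), max(img))
})

test_that("register_stack anchors the reference and recovers the misalignments", {
  stk <- fixture_stack5()
  lms <- lapply(1:5, function(s) {
    tru <- stk$truth$landmarks[stk$truth$landmarks$section == s - 1, ]
    landmark_set(as.matrix(tru[, c("row", "col")]), s - 1L)
  })
  reg <- register_stack(stk$sections, lms, 0)
  expect_length(reg$registered, 5)
  expect_identical(reg$registered[[1]], stk$sections[[1]])
  expect_equal(reg$transforms[[1]]$a, c(0, 1, 0, 0))

  # fitted transforms agree with the generating misalignment at the landmarks
  for (s in 2:5) {
    obs <- as.matrix(stk$truth$landmarks[stk$truth$landmarks$section == s - 1,
                                         c("row", "col")])
    res <- apply_bilinear(reg$transforms[[s]], obs) -
      apply_bilinear(stk$truth$transforms[[s]], obs)
    expect_lt(max(abs(res)), 1e-6)
  }

  # per-label scatter of registered landmarks collapses to ~0
  regd <- lapply(1:5, function(s) apply_bilinear(reg$transforms[[s]],
                                                 lms[[s]]$centers))
  for (k in 1:4) {
    pts <- t(vapply(regd, function(m) m[k, ], numeric(2)))
    expect_lt(sqrt(mean(rowSums(sweep(pts, 2, colMeans(pts))^2))), 0.5)
  }
})

test_that("register_stack skips sections without landmarks and reports gaps", {
  stk <- fixture_stack5()
  lms <- lapply(1:5, function(s) {
    tru <- stk$truth$landmarks[stk$truth$landmarks$section == s - 1, ]
    landmark_set(as.matrix(tru[, c("row", "col")]), s - 1L)
  })
  lms[3] <- list(NULL)
  expect_warning(reg <- register_stack(stk$sections, lms, 0), "gap")
  expect_equal(reg$gaps, 2L)
  expect_null(reg$registered[[3]])
  expect_error(register_stack(stk$sections, list(NULL, lms[[2]], NULL, NULL, NULL), 0),
               class = "fascicle3d_registration_error")
})

test_that("transform composition is consistent at the control points", {
  ref <- ref_square()
  set.seed(9)
  jitter <- function() ref + matrix(runif(8, -4, 4), 4, 2)
  A <- jitter(); B <- jitter(); C <- jitter()
  ab <- fit_bilinear(B, A); bc <- fit_bilinear(C, B); ac <- fit_bilinear(C, A)
  expect_lt(max(abs(apply_bilinear(bc, apply_bilinear(ab, A)) -
                      apply_bilinear(ac, A))), 1e-6)
})

test_that("invert_bilinear_at is a true pointwise inverse", {
  t <- bilinear_transform(c(2, 1.02, -0.05, 1e-5), c(-3, 0.04, 0.98, -2e-5))
  pts <- cbind(runif(20, 0, 200), runif(20, 0, 260))
  q <- apply_bilinear(t, pts)
  back <- invert_bilinear_at(t, q)
  expect_lt(max(abs(back - pts)), 1e-9)
})
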