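test_that("LS-SVM training solves the dual system deterministically", {
  w <- fixture_windows()
  m1 <- lssvm_train(w$features, w$y, 20, 100)
  m2 <- lssvm_train(w$features, w$y, 20, 100)
  expect_identical(m1$alpha, m2$alpha)
  expect_identical(m1$b, m2$b)
  expect_length(m1$alpha, nrow(w$features))  # every point keeps a coefficient

  # two distinct one-per-class points are separated for any valid parameters
  x <- rbind(rep(0, 4), rep(1, 4))
  for (s2 in c(0.5, 2, 20)) {
    m <- lssvm_train(x, c(-1, 1), s2, 10)
    expect_equal(lssvm_predict(m, x), c(-1, 1))
  }

  # hard-margin limit: training error -> 0 as gamma grows
  mh <- lssvm_train(w$features, w$y, 20, 1e6)
  expect_equal(lssvm_error(mh, w$features, w$y), 0)
})

test_that("GA tuning beats or matches the untuned baseline on a held-out set", {
  train <- fixture_windows()
  test <- generate_template_windows(120, 120, seed = 4)
  baseline <- lssvm_train(train$features, train$y, 2, 100)
  err_base <- lssvm_error(baseline, test$features, test$y)
  tuned <- tune_detector(train, test,
                         list(pop_size = 10L, generations = 5L, seed = 1L))
  expect_lte(tuned$test_error, err_base)
  # on this synthetic split the untuned kernel is strictly worse
  expect_gt(err_base, tuned$test_error)
  expect_gte(tuned$sigma2, 0.1); expect_lte(tuned$sigma2, 50)
  expect_gte(tuned$gamma, 1); expect_lte(tuned$gamma, 1000)
})

test_that("GA with collapsed bounds returns exactly that point", {
  res <- tune_detector(
    generate_template_windows(20, 20, 1), generate_template_windows(20, 20, 2),
    list(bounds = rbind(c(5, 50), c(5, 50)), pop_size = 6L,
         generations = 2L, seed = 1L))
  expect_equal(res$sigma2, 5)
  expect_equal(res$gamma, 50)
  expect_error(tune_detector(fixture_windows(),
                             list(features = matrix(0, 0, 225), y = numeric(0))),
               class = "fascicle3d_config_error")
})

test_that("detection finds all four landmarks within 1 px on synthetic sections", {
  stk <- fixture_stack5()
  model <- fixture_detector()
  for (s in 1:5) {
    lm <- detect_position_lines(stk$sections[[s]], model)
    expect_equal(nrow(lm$centers), 4L)
    expect_equal(rownames(lm$centers), c("S_a", "S_b", "S_c", "S_d"))
    expect_equal(lm$section_center, colMeans(lm$centers))
    tru <- as.matrix(stk$truth$landmarks[stk$truth$landmarks$section == s - 1,
                                         c("row", "col")])
    d <- sqrt(outer(tru[, 1], lm$centers[, 1], "-")^2 +
                outer(tru[, 2], lm$centers[, 2], "-")^2)
    expect_lt(max(apply(d, 1, min)), 1)
  }
})

test_that("an image without dark blobs raises DetectionCountError(0)", {
  blank <- array(0.9, c(60, 60, 3))
  err <- tryCatch(detect_position_lines(blank, fixture_detector()),
                  fascicle3d_detection_count_error = function(e) e)
  expect_s3_class(err, "fascicle3d_detection_count_error")
  expect_equal(err$count, 0L)
})

test_that("a centred blob is circle-like and the same blob shifted 4 px is not", {
  model <- fixture_detector()
  w <- generate_template_windows(30, 1, seed = 21)
  centred <- w$windows[[5]]
  expect_gt(lssvm_decision(model, window_features(list(centred))), 0)
  shifted <- array(0.85, c(15, 15, 3))
  shifted[5:15, , ] <- centred[1:11, , ]
  expect_lt(lssvm_decision(model, window_features(list(shifted))), 0)
})

test_that("detection is equivariant under integer translation", {
  stk <- fixture_stack5()
  model <- fixture_detector()
  img <- stk$sections[[1]]
  rows <- dim(img)[1]; cols <- dim(img)[2]
  dr <- 6L; dc <- -4L
  shifted <- array(0.85, dim(img))
  shifted[(1 + dr):rows, 1:(cols + dc), ] <- img[1:(rows - dr), (1 - dc):cols, ]
  lm0 <- detect_position_lines(img, model)
  lm1 <- detect_position_lines(shifted, model)
  expect_equal(lm1$centers, lm0$centers + matrix(rep(c(dr, dc), each = 4), 4),
               tolerance = 1e-12)
})

test_that("the ring template and canonical labelling behave as documented", {
  rt <- ring_template()
  expect_equal(rt$size, 15L)
  expect_equal(rt$center_index, c(7L, 7L))
  expect_true(rt$band_mask[8, 1])    # (7,0): distance 7 is inside the band
  expect_false(rt$band_mask[8, 8])   # the centre is not

  centers <- rbind(c(10, 10), c(10, 90), c(90, 90), c(90, 10))
  ls <- landmark_set(centers[sample(4), ])
  # counterclockwise from smallest angle in (x=col, y=-row) orientation
  expect_equal(unname(ls$centers["S_a", ]), c(10, 90))
  expect_equal(unname(ls$centers["S_b", ]), c(10, 10))
  expect_equal(unname(ls$centers["S_c", ]), c(90, 10))
  expect_equal(unname(ls$centers["S_d", ]), c(90, 90))
})

test_that("a detector archive round-trips through JSON", {
  model <- fixture_detector()
  p <- tempfile(fileext = ".json")
  save_detector(model, p)
  back <- load_detector(p)
  w <- generate_template_windows(10, 10, seed = 30)
  expect_equal(lssvm_decision(back, w$features),
               lssvm_decision(model, w$features), tolerance = 1e-12)
})
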