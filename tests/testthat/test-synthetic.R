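test_that("stack generation is deterministic under a fixed seed", {
  cfg <- stack_config(n_sections = 2, image_size = c(160, 200),
                      n_fascicles_initial = 2, misalignment_scale = 3,
                      rng_seed = 42)
  a <- generate_stack(cfg)
  b <- generate_stack(cfg)
  expect_identical(a$sections, b$sections)
  expect_identical(a$truth$landmarks, b$truth$landmarks)
})

test_that("config validation rejects bad inputs", {
  expect_error(stack_config(landmark_diameter_px = 11), "12")
  expect_error(stack_config(n_sections = 4, split_merge_events =
    list(list(section = 9, event = "merge", fascicle = 1))), "range")
  expect_error(stack_config(split_merge_events =
    list(list(section = 2, event = "explode", fascicle = 1))), "split")
  # splitting a circle-born fascicle (a fresh split child) is rejected
  cfg <- stack_config(n_sections = 4, image_size = c(200, 260),
                      n_fascicles_initial = 2, split_merge_events =
                        list(list(section = 1, event = "split", fascicle = 1),
                             list(section = 2, event = "split", fascicle = 3)),
                      rng_seed = 1)
  expect_error(generate_stack(cfg), class = "fascicle3d_config_error")
})

test_that("a merge event removes one fascicle and builds the lineage edge", {
  cfg <- stack_config(n_sections = 5, image_size = c(200, 260),
                      n_fascicles_initial = 3, split_merge_events =
                        list(list(section = 2, event = "merge", fascicle = 1)),
                      misalignment_scale = 0, rng_seed = 5)
  stk <- generate_stack(cfg)
  counts <- truth_counts(stk$truth)
  expect_equal(counts[4], counts[2] - 1L)    # section 3 vs section 1
  lin <- stk$truth$lineage
  expect_equal(sum(lin$event == "merge"), 2L)  # two parent edges, one child
  expect_equal(length(unique(lin$child[lin$event == "merge"])), 1L)
  # merge node has in-degree 2, graph is a forest over the edges
  expect_equal(nrow(lin[lin$event == "merge", ]), 2L)
})

test_that("zero misalignment records identity transforms", {
  stk <- fixture_section()
  expect_equal(stk$truth$transforms[[1]]$a, c(0, 1, 0, 0))
  expect_equal(stk$truth$transforms[[1]]$b, c(0, 0, 1, 0))
})

test_that("every section carries exactly 4 landmarks with sane geometry", {
  stk <- fixture_stack5()
  lm <- stk$truth$landmarks
  expect_equal(as.integer(table(lm$section)), rep(4L, 5))
  expect_setequal(unique(lm$label), c("S_a", "S_b", "S_c", "S_d"))
  d <- stk$truth$config$landmark_diameter_px
  expect_gte(d, 12); expect_lte(d, 15)
})

test_that("texture classes order as sensory < mixed < motor in mean gray", {
  stk <- fixture_section()
  gray <- rgb_to_gray(stk$sections[[1]])
  tm <- stk$truth$masks[[1]]
  means <- vapply(sort(unique(tm[tm > 0])), function(id)
    mean(gray[tm == id]), numeric(1))
  names(means) <- stk$truth$types[as.character(sort(unique(tm[tm > 0])))]
  expect_lt(means[["sensory"]], means[["mixed"]])
  expect_lt(means[["mixed"]], means[["motor"]])
})

test_that("lineage masks align across consecutive sections after inverse warp", {
  stk <- fixture_canonical()
  worst <- 1
  for (s in 1:15) {
    a <- truth_contours_aligned(stk, s)
    b <- truth_contours_aligned(stk, s + 1)
    for (id in intersect(names(a), names(b))) {
      ma <- rasterize_polygon(a[[id]], 240, 320)
      mb <- rasterize_polygon(b[[id]], 240, 320)
      worst <- min(worst, mask_jaccard(ma, mb))
    }
  }
  expect_gte(worst, 0.99)
})

test_that("template windows have the contracted shape, labels and band geometry", {
  w <- generate_template_windows(1, 1, seed = 9)
  expect_length(w$windows, 2)
  expect_setequal(w$labels, c("circle", "noncircle"))
  expect_true(all(vapply(w$windows, function(x)
    identical(dim(x), c(15L, 15L, 3L)), logical(1))))

  # positive blob edges fall inside the ring band
  rt <- ring_template()
  big <- generate_template_windows(25, 1, seed = 9)
  for (i in 1:25) {
    g <- rgb_to_gray(big$windows[[i]])
    blob <- g < 0.5
    edge <- blob & !(blob[c(1, 1:14), ] & blob[c(2:15, 15), ] &
                       blob[, c(1, 1:14)] & blob[, c(2:15, 15)])
    expect_true(all(rt$band_mask[edge]))
  }
  # determinism
  expect_identical(generate_template_windows(5, 5, seed = 1),
                   generate_template_windows(5, 5, seed = 1))
})

test_that("stack and ground-truth writers produce readable artifacts", {
  stk <- fixture_section()
  d <- tempfile("stackio")
  write_stack(stk, d)
  back <- read_stack(d)
  expect_length(back, 1)
  expect_lt(max(abs(back[[1]] - stk$sections[[1]])), 1 / 254)
  write_ground_truth(stk$truth, file.path(d, "truth"))
  expect_true(file.exists(file.path(d, "truth", "landmarks.csv")))
  expect_true(file.exists(file.path(d, "truth", "transforms.csv")))
  expect_true(file.exists(file.path(d, "truth", "mask_000.pgm")))
  lab <- read_pgm_labels(file.path(d, "truth", "mask_000.pgm"))
  expect_identical(lab, stk$truth$masks[[1]])
  unlink(d, recursive = TRUE)
})
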