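test_that("blank images segment to zero cells with a warning", {
  blank <- channel_image(matrix(0, 32, 32), modality = "c60_protein")
  expect_warning(lab <- segment_cells(blank, blank), "blank")
  expect_equal(n_cells(lab), 0)
  expect_equal(nrow(integrate_cells(lab, list(x = blank))), 0)
})

test_that("non-touching cells are counted exactly", {
  ph <- generate_phantom(phantom_spec(image_shape = c(192, 192), n_cells = 50,
                                      cell_radius = c(4, 6)),
                         "control", seed = 13)
  lab <- segment_cells(ph$protein$nuclear, ph$protein$membrane)
  expect_equal(n_cells(lab), 50)
})

test_that("touching cells split along the membrane ridge", {
  d <- touching_disks()
  lab <- segment_cells(d$nuclear, d$membrane, min_area = 30)
  expect_equal(n_cells(lab), 2)
})

test_that("segmentation is deterministic", {
  ph <- generate_phantom(phantom_spec(image_shape = c(128, 128), n_cells = 20),
                         "control", seed = 2)
  l1 <- segment_cells(ph$protein$nuclear, ph$protein$membrane)
  l2 <- segment_cells(ph$protein$nuclear, ph$protein$membrane)
  expect_identical(l1$labels, l2$labels)
})

test_that("per-cell integration partitions the labeled pixels exactly", {
  lab <- label_map(matrix(c(0, 1, 1, 0, 1, 1, 0, 0, 0, 2, 2, 2, 0, 2, 0, 0),
                          4, 4))
  const2 <- channel_image(matrix(2, 4, 4))
  rec <- integrate_cells(lab, list(c2 = const2))
  expect_equal(rec$c2[rec$cell_id == 1], 8)  # 4-pixel cell on a constant-2 channel
  expect_equal(rec$area, c(4, 4))
  set.seed(77)
  img <- channel_image(matrix(runif(16), 4, 4))
  rec2 <- integrate_cells(lab, list(r = img))
  expect_identical(sum(rec2$r), sum(img$values[lab$labels > 0]))
  expect_error(integrate_cells(lab, list(channel_image(matrix(1, 2, 2)))),
               "shape")
})

test_that("marker thresholds recover the designed type fractions", {
  ph <- generate_phantom(phantom_spec(image_shape = c(192, 192),
                                      n_cells = 60), "control", seed = 31)
  lab <- segment_cells(ph$protein$nuclear, ph$protein$membrane)
  rec <- integrate_cells(lab, ph$protein)
  rules <- list(cell_type_rule("K14+", "K14", threshold = "otsu"),
                cell_type_rule("panCK+K14-", "panCK",
                               threshold = "half_median"))
  rec <- classify_cells(rec, rules)
  truth_frac <- mean(ph$truth$cells$cell_type == "K14+")
  est_frac <- mean(rec$cell_type == "K14+")
  expect_lt(abs(est_frac - truth_frac), 0.05)
  expect_false(any(rec$cell_type == "unassigned"))
  # all cells above a trivially low manual threshold are typed by rule 1
  all_k14 <- classify_cells(rec[1:4, ], list(cell_type_rule("K14+", "K14",
                                                          threshold = 0)))
  expect_true(all(all_k14$cell_type == "K14+"))
  # a cell below every threshold stays unassigned
  none <- classify_cells(rec[1:4, ], list(cell_type_rule("K14+", "K14",
                                                       threshold = Inf)))
  expect_true(all(none$cell_type == "unassigned"))
  expect_error(classify_cells(rec, list(cell_type_rule("x", "absent"))),
               "absent")
})

test_that("hierarchical clustering separates well-separated populations", {
  set.seed(5)
  n <- 60
  rec <- data.frame(cell_id = 1:(2 * n), area = 1,
                    a = c(rnorm(n, 0), rnorm(n, 8)),
                    b = c(rnorm(n, 0), rnorm(n, 8)))
  cl <- cluster_cells(rec, c("a", "b"), k = 2)
  truth <- rep(1:2, each = n)
  agree <- max(mean(cl$assignments == truth),
               mean(cl$assignments == 3 - truth))
  expect_gte(agree, 0.95)
  # duplicated record list gives an identical tree topology
  cl2 <- cluster_cells(rec, c("a", "b"), k = 2)
  expect_identical(cl$tree$merge, cl2$tree$merge)
  # nearest points merge first
  tiny <- data.frame(cell_id = 1:3, area = 1, v = c(0, 0.1, 10))
  tr <- cluster_cells(tiny, "v")$tree
  expect_equal(sort(-tr$merge[1, ]), c(1, 2))
  expect_error(cluster_cells(tiny[1, ], "v"), "at least 2")
})

test_that("cell-type comparison matches the Welch formula", {
  rec <- data.frame(cell_id = 1:8, area = 1,
                    ox = c(1, 2, 3, 4, 1, 2, 3, 4),
                    cell_type = rep(c("K14+", "panCK+K14-"), each = 4))
  same <- compare_celltypes(rec, "ox", "K14+", "panCK+K14-")
  expect_equal(same$t_statistic, 0)
  expect_equal(same$p_value, 1)
  set.seed(3)
  a <- rnorm(50, 3, 1)
  b <- rnorm(50, 0, 1)
  rec2 <- data.frame(cell_id = 1:100, area = 1, ox = c(a, b),
                     cell_type = rep(c("K14+", "panCK+K14-"), each = 50))
  cmp <- compare_celltypes(rec2, "ox", "K14+", "panCK+K14-")
  expect_lt(cmp$p_value, 0.001)
  expect_equal(cmp$t_statistic, welch_t_oracle(a, b), tolerance = 1e-10)
  expect_equal(cmp$mean_a, mean(a))
  expect_equal(cmp$sd_b, sd(b))
  expect_error(compare_celltypes(rec2[c(1, 51:100), ], "ox", "K14+",
                                 "panCK+K14-"), "at least 2")
})

test_that("VIP scores are normalized and flag the discriminating variable", {
  set.seed(10)
  X <- matrix(rnorm(300), 30, 10)
  y <- rep(0:1, 15)
  v <- plsda_vip(X, y)
  expect_equal(mean(v$scores^2), 1, tolerance = 1e-10)
  first <- 0
  for (s in 1:20) {
    set.seed(s)
    X <- matrix(rnorm(100 * 10), 100, 10)
    y <- rep(0:1, each = 50)
    X[y == 1, 1] <- X[y == 1, 1] + 1
    v <- plsda_vip(X, y)
    expect_equal(mean(v$scores^2), 1, tolerance = 1e-10)
    if (which.max(v$scores) == 1) first <- first + 1
    if (s == 1) expect_gt(v$scores[1], 1)
  }
  expect_gte(first, 19)
  expect_error(plsda_vip(X, rep(1, 100)), "2 classes")
})

test_that("VIP agrees with an independent PLS-DA implementation", {
  skip_if_not_installed("mixOmics")
  set.seed(41)
  n <- 60
  p <- 8
  X <- matrix(rnorm(n * p), n, p)
  y <- rep(c("ctrl", "les"), each = n / 2)
  X[y == "les", 3] <- X[y == "les", 3] + 1.5
  X[y == "les", 6] <- X[y == "les", 6] - 0.8
  mine <- plsda_vip(X, y, n_components = 2)
  Xs <- scale(X)
  ref <- mixOmics::vip(mixOmics::plsda(Xs, factor(y), ncomp = 2,
                                       scale = FALSE))
  expect_equal(unname(mine$scores), unname(ref[, 2]), tolerance = 1e-6)
})
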