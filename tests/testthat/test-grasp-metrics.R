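test_that("similarity identities hold", {
  g <- c(0, 0, 0, 10, 20, 5)
  expect_equal(grasp_similarity(g, g, 100)$value, 100)
  # thumbs separated by exactly d_max, shared index: 0%
  g1 <- c(0, 0, 0, 5, 5, 5); g2 <- c(120, 0, 0, 5, 5, 5)
  expect_equal(grasp_similarity(g1, g2, 120)$value, 0, tolerance = 1e-12)
  # half of d_max: 50%
  g3 <- c(60, 0, 0, 5, 5, 5)
  expect_equal(grasp_similarity(g1, g3, 120)$value, 50, tolerance = 1e-12)
  # 6D distances can exceed the 3D extent: unclamped goes negative
  g4 <- c(120, 0, 0, 5, 125, 5)
  expect_lt(grasp_similarity(g1, g4, 120)$value, 0)
  expect_identical(grasp_similarity(g1, g4, 120, clamp = TRUE)$value, 0)
  # symmetry and joint rigid-motion invariance
  tf <- rigid_transform(rotation_about(c(1, 2, 3), 40), c(5, -8, 12))
  move <- function(g) c(transform_points(tf, g[1:3]),
                        transform_points(tf, g[4:6]))
  expect_equal(grasp_similarity(g1, g2, 120)$value,
               grasp_similarity(g2, g1, 120)$value)
  expect_equal(grasp_similarity(move(g1), move(g2), 120)$value,
               grasp_similarity(g1, g2, 120)$value, tolerance = 1e-9)
})

test_that("medoid minimizes total 6D distance, ties to the first member", {
  one <- grasp_table(c(1, 2, 3), c(4, 5, 6))
  expect_equal(medoid_grasp(one), one)
  # three collinear grasps: the middle one wins
  tri <- grasp_table(rbind(c(0, 0, 0), c(10, 0, 0), c(30, 0, 0)),
                     matrix(0, 3, 3))
  expect_equal(as.numeric(grasp_matrix(medoid_grasp(tri))[1, 1]), 10)
  # random sets agree with the exhaustive oracle
  set.seed(14)
  for (rep in 1:20) {
    g <- grasp_table(matrix(rnorm(21), 7), matrix(rnorm(21), 7))
    d <- as.matrix(dist(grasp_matrix(g)))
    expect_identical(rownames(medoid_grasp(g)),
                     rownames(g)[which.min(rowSums(d))])
  }
})

test_that("within/between similarity orders clustered synthetic subjects", {
  cands <- fx_cands("L")
  obj <- fx_L()
  g <- simulate_clustered_grasps(cands, n_subjects = 6, n_trials = 8,
                                 sigma_within = 4, seed = 10)
  wb <- within_between_similarity(g, obj$d_max)
  expect_gt(mean(wb$within), mean(wb$between))
  # identical grasps for everyone: both 100%
  same <- grasp_table(matrix(1:3, 12, 3, byrow = TRUE),
                      matrix(4:6, 12, 3, byrow = TRUE))
  same$subject <- rep(1:3, each = 4)
  wb_same <- within_between_similarity(same, obj$d_max)
  expect_equal(wb_same$within, rep(100, 3))
  expect_equal(wb_same$between, rep(100, 3))
  # doubling all coordinates and d_max changes nothing
  g2 <- g; g2[, graspsel:::grasp_columns] <- 2 * g[, graspsel:::grasp_columns]
  wb2 <- within_between_similarity(g2, 2 * obj$d_max)
  expect_equal(wb2$within, wb$within, tolerance = 1e-9)
  expect_equal(wb2$between, wb$between, tolerance = 1e-9)
  single <- g[g$subject == 1, ]
  expect_true(all(is.na(within_between_similarity(single,
                                                  obj$d_max)$between)))
})

test_that("random-grasp chance level is seeded and matches a direct oracle", {
  cands <- fx_cands("L")
  obj <- fx_L()
  ch1 <- random_grasp_baseline(cands, obj$d_max, n = 80, seed = 6,
                               n_boot = 500)
  ch2 <- random_grasp_baseline(cands, obj$d_max, n = 80, seed = 6,
                               n_boot = 500)
  expect_identical(ch1$value, ch2$value)
  expect_identical(ch1$ci, ch2$ci)
  expect_true(ch1$ci[1] <= ch1$value && ch1$value <= ch1$ci[2])
  # oracle: mean similarity of the returned sample to its medoid
  med <- medoid_grasp(ch1$grasps)
  sims <- vapply(seq_len(nrow(ch1$grasps)), function(i)
    grasp_similarity(ch1$grasps[i, ], med, obj$d_max)$value, 0)
  expect_equal(ch1$value, mean(sims), tolerance = 1e-12)
  # two-candidate degenerate object: enumerable distribution
  two <- manual_cands(c(0, 0, 0, 30, 0, 0), rep(c(0, 0, 1), 2))
  ch <- random_grasp_baseline(two, 30, n = 40, seed = 1, n_boot = 100)
  # only pairs (1,2) and (2,1) exist, at 6D distance 30*sqrt(2); the medoid
  # is the majority pair, so mean similarity is 100 - minority share scaled
  tab <- table(ch$grasps$thumb_cand)
  minority <- min(tab) / sum(tab)
  expect_equal(ch$value,
               100 * (1 - minority * sqrt(2)), tolerance = 1e-9)
  # clustered subjects sit well above chance
  g <- simulate_clustered_grasps(cands, 6, 8, sigma_within = 4, seed = 10)
  wb <- within_between_similarity(g, obj$d_max)
  expect_gt(mean(wb$within), ch1$value)
})

test_that("CoM attraction is zero for random grasps, maximal at the CoM", {
  obj <- fx_L()
  cands <- fx_cands("L")
  # self-comparison: observed grasps are themselves a uniform sample
  vals <- vapply(1:50, function(s) {
    obs <- random_grasps(cands, 60, seed = 1000 + s)
    com_attraction(obs, obj, cands, baseline_n = 60,
                   seed = 2000 + s)$attraction
  }, 0)
  expect_lt(abs(mean(vals)), 2 * stats::sd(vals) / sqrt(50))
  # all midpoints at the CoM: attraction equals the mean random CoM distance
  com <- object_com(obj)
  at_com <- grasp_table(matrix(com + c(0, -10, 0), 5, 3, byrow = TRUE),
                        matrix(com + c(0, 10, 0), 5, 3, byrow = TRUE))
  res <- com_attraction(at_com, obj, cands, baseline_n = 500, seed = 3)
  expect_equal(res$attraction, res$random_mean, tolerance = 1e-12)
  expect_equal(res$observed_mean, 0, tolerance = 1e-12)
})

test_that("spatial bias measures approach toward the start location", {
  obj <- fx_L()
  start <- c(280, 95, 0)
  centroid <- object_centroid(obj)
  centered <- grasp_table(matrix(centroid + c(-5, 0, 0), 4, 3, byrow = TRUE),
                          matrix(centroid + c(5, 0, 0), 4, 3, byrow = TRUE))
  expect_equal(spatial_bias(centered, obj, start), 0, tolerance = 1e-9)
  # constructed case: grasps 30 mm from the start along the start-centroid
  # line are closer by exactly dist(start, centroid) - 30
  dirv <- (centroid - start) / sqrt(sum((centroid - start)^2))
  near <- start + 30 * dirv
  g <- grasp_table(near, near)
  expect_equal(spatial_bias(g, obj, start),
               sqrt(sum((centroid - start)^2)) - 30, tolerance = 1e-9)
  # translating the whole scene leaves the bias unchanged
  shift <- c(12, -7, 3)
  obj2 <- set_pose(obj, rigid_transform(diag(3), shift))
  g2 <- grasp_table(near + shift, near + shift)
  expect_equal(spatial_bias(g2, obj2, start + shift),
               spatial_bias(g, obj, start), tolerance = 1e-9)
})

test_that("egocentric and allocentric encodings behave as constructed", {
  obj <- fx_L()
  pose_a <- rigid_transform(diag(3), c(0, 100, 0))
  pose_b <- compose_transforms(rigid_transform(rotation_about("z", 90),
                                               c(0, 100, 0)), rigid_transform())
  g_a <- grasp_table(transform_points(pose_a, c(10, 0, 30)),
                     transform_points(pose_a, c(10, 25, 30)))
  # grasp co-rotated with the object: allocentric similarity 100%
  g_b <- grasp_table(transform_points(pose_b, c(10, 0, 30)),
                     transform_points(pose_b, c(10, 25, 30)))
  alo_a <- encode_frame(g_a, pose_a, "allocentric")
  alo_b <- encode_frame(g_b, pose_b, "allocentric")
  expect_equal(grasp_similarity(alo_a, alo_b, obj$d_max)$value, 100,
               tolerance = 1e-9)
  expect_lt(grasp_similarity(g_a, g_b, obj$d_max)$value, 100)
  # grasp fixed in the world across a 180 degree rotation: egocentric 100%
  pose_c <- compose_transforms(rigid_transform(rotation_about("z", 180),
                                               c(0, 100, 0)), rigid_transform())
  alo_c <- encode_frame(g_a, pose_c, "allocentric")
  expect_equal(grasp_similarity(g_a, g_a, obj$d_max)$value, 100)
  expect_lt(grasp_similarity(alo_a, alo_c, obj$d_max)$value, 100)
  # identical poses: the two encodings agree up to a fixed transform
  expect_identical(encode_frame(g_a, pose_a, "egocentric"), g_a)
})
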