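test_that("rigid transforms validate, compose and invert", {
  expect_error(rigid_transform(matrix(1, 3, 3)), "orthonormal")
  R <- rotation_from_euler(c(10, -20, 30))
  expect_equal(crossprod(R), diag(3), tolerance = 1e-12)
  tr <- rigid_transform(R, c(1, 2, 3))
  pts <- matrix(rnorm(30), 10, 3)
  back <- apply_transform(invert_transform(tr), apply_transform(tr, pts))
  expect_equal(back, pts, tolerance = 1e-12)
  comp <- compose_transform(tr, invert_transform(tr))
  expect_equal(comp$rotation, diag(3), tolerance = 1e-12)
  expect_equal(comp$translation, c(0, 0, 0), tolerance = 1e-12)
  # homogeneous matrix and JSON round trip
  expect_equal(transform_from_matrix(transform_to_matrix(tr)), tr)
  path <- withr::local_tempfile(fileext = ".json")
  write_transform(tr, path)
  expect_equal(read_transform(path), tr, tolerance = 1e-12)
})

test_that("closest_point is exact on hand and brute-force cases", {
  tri <- surface_mesh(matrix(c(0, 0, 0, 4, 0, 0, 0, 4, 0), 3, byrow = TRUE),
                      matrix(1:3, 1))
  # query above the interior projects orthogonally
  r <- closest_point(c(1, 1, 5), tri)
  expect_equal(as.vector(r$point), c(1, 1, 0))
  expect_equal(r$distance, 5)
  # vertex query returns the vertex at distance 0
  r <- closest_point(c(4, 0, 0), tri)
  expect_equal(r$distance, 0)
  # edge region
  r <- closest_point(c(3, 3, 0), tri)
  expect_equal(as.vector(r$point), c(2, 2, 0))

  mesh <- ellipsoid_mesh()
  set.seed(42)
  q <- matrix(runif(300, -14, 14), 100, 3)
  fast <- closest_point(q, mesh)
  for (i in seq_len(20)) {   # exhaustive oracle on a subset
    expect_equal(fast$distance[i], closest_point_mesh_oracle(q[i, ], mesh),
                 tolerance = 1e-9)
  }
  # returned point realises the distance
  expect_equal(sqrt(rowSums((q - fast$point)^2)), fast$distance,
               tolerance = 1e-9)
  expect_error(closest_point(c(0, 0, 0), surface_mesh(matrix(0, 1, 3),
                                                      matrix(0L, 0, 3))),
               "no faces")
})

test_that("ICP recovers exact and noisy rigid transforms", {
  mesh <- ellipsoid_mesh()
  # self-registration: identity at RMS ~ 0
  reg <- icp_register(mesh, mesh)
  expect_lt(reg$rms, 1e-10)
  expect_equal(reg$transform$rotation, diag(3), tolerance = 1e-8)

  # known transform: 10 deg about z + (3, -2, 1) mm
  cl <- generate_transformed_cloud(mesh, angles = c(0, 0, 10),
                                   translation = c(3, -2, 1))
  reg <- icp_register(cl$points, mesh)
  err <- compose_transform(reg$transform, cl$transform)
  expect_lt(rotation_angle(err$rotation), 1e-3)
  expect_lt(max(abs(err$translation)), 1e-3)
  expect_true(all(diff(reg$rms_history) <= 1e-12))

  # noisy cloud: RMS near the noise level, rotation within half a degree
  cl <- generate_transformed_cloud(mesh, angles = c(0, 0, 5),
                                   translation = c(1, -1, 0.5),
                                   noise_sigma = 0.1, seed = 11)
  reg <- icp_register(cl$points, mesh)
  expect_gt(reg$rms, 0.05); expect_lt(reg$rms, 0.2)
  err <- compose_transform(reg$transform, cl$transform)
  expect_lt(rotation_angle(err$rotation) * 180 / pi, 0.5)
  expect_true(all(diff(reg$rms_history) <= 1e-12))

  # degenerate source
  line <- cbind(1:10, 1:10, 1:10)
  expect_error(icp_register(line, mesh), "collinear")
})

test_that("ICP is equivariant under pre-transformation of the source", {
  mesh <- ellipsoid_mesh()
  src <- mesh$vertices[seq(1, nrow(mesh$vertices), by = 7), ]
  T1 <- rigid_transform(rotation_from_euler(c(2, -3, 4)), c(0.5, 1, -0.7))
  reg_a <- icp_register(apply_transform(T1, src), mesh)
  reg_b <- icp_register(src, mesh, init = T1)
  # the two runs are step-identical, so the recovered world alignments match
  comp <- compose_transform(reg_a$transform, T1)
  expect_equal(comp$rotation, reg_b$transform$rotation, tolerance = 1e-6)
  expect_equal(comp$translation, reg_b$transform$translation,
               tolerance = 1e-6)
})

test_that("deviation fields have the right sign and magnitude", {
  s10 <- sphere_mesh(10, half = 13, step = 0.5)
  # identical meshes: zero deviation
  dev <- deviation_map(s10, s10, register = FALSE)
  expect_lt(max(abs(dev$d_mm)), 1e-9)
  # offset spheres: +1 outside, -1 inside, sign flips when swapped
  s11 <- sphere_mesh(11, half = 13, step = 0.5)
  s9 <- sphere_mesh(9, half = 13, step = 0.5)
  d_out <- deviation_map(s11, s10, register = FALSE)$d_mm
  d_in <- deviation_map(s9, s10, register = FALSE)$d_mm
  expect_equal(mean(d_out), 1, tolerance = 0.15)
  expect_equal(mean(d_in), -1, tolerance = 0.15)
  expect_true(all(d_out > 0) && all(d_in < 0))
})

test_that("deviation summaries bin, average and cover correctly", {
  s <- summarize_deviation(rep(0, 100), threshold = 0.227)
  expect_equal(s$mean, 0)
  expect_equal(s$coverage, 100)
  expect_equal(sum(s$bins$percent), 100, tolerance = 1e-6)
  zero_bin <- which(s$bins$lower <= 0 & s$bins$upper > 0)
  expect_equal(s$bins$percent[zero_bin], 100)

  s <- summarize_deviation(c(rep(0.5, 50), rep(-0.5, 50)))
  expect_equal(s$mean, 0)
  expect_equal(s$coverage, 0)

  # seeded Gaussian field vs the closed-form Normal probability
  set.seed(5)
  d <- rnorm(1e4, mean = 0.01, sd = 0.1)
  s <- summarize_deviation(d)
  expect_lt(abs(s$mean - 0.01), 0.003)
  p <- pnorm((0.227 - 0.01) / 0.1) - pnorm((-0.227 - 0.01) / 0.1)
  expect_lt(abs(s$coverage - 100 * p), 2)

  expect_error(summarize_deviation(d, bin_edges = c(1, 0, -1)), "increasing")
  expect_error(summarize_deviation(numeric(0)), "empty")
  # glance/tidy accessors
  expect_equal(nrow(tidy(s)), 13)
  expect_named(glance(s), c("mean_mm", "coverage_pct", "threshold_mm", "n"))
})

test_that("deviation colors follow the diverging blue-green-red map", {
  cols <- colorize_deviation(c(-2, -1, -0.5, 0, 0.5, 1, 2), range = 1)
  expect_equal(cols$hex[4], "#00FF00")                  # 0 -> green
  expect_equal(unlist(cols[6, c("r", "g", "b")]), c(r = 1, g = 0, b = 0))
  expect_equal(unlist(cols[5, c("r", "g", "b")]), c(r = 0.5, g = 0.5, b = 0))
  expect_equal(cols$hex[1], cols$hex[2])                # clamped
  expect_equal(cols$hex[7], cols$hex[6])
  expect_error(colorize_deviation(0, range = 0), "positive")
})
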