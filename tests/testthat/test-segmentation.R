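test_that("Sobel gradient matches hand-convolved cases", {
  # flat image: zero gradient everywhere (interior and reflect-padded border)
  g <- sobel_gradient(matrix(5, 8, 8))
  expect_equal(max(abs(g$magnitude)), 0)

  # horizontal unit step: magnitude 4 on the two rows adjacent to the step,
  # 0 away from it (hand convolution of the 3x3 kernels)
  sl <- matrix(0, 8, 8); sl[5:8, ] <- 1
  g <- sobel_gradient(sl)
  expect_equal(unname(g$magnitude[4, 4]), 4)
  expect_equal(unname(g$magnitude[5, 4]), 4)
  expect_equal(unname(g$magnitude[2, 4]), 0)
  expect_equal(unname(g$magnitude[7, 4]), 0)

  # single bright pixel: response confined to its 3x3 neighbourhood
  sl <- matrix(0, 9, 9); sl[5, 5] <- 1
  w <- which(sobel_gradient(sl)$magnitude > 0, arr.ind = TRUE)
  expect_true(all(abs(w[, 1] - 5) <= 1 & abs(w[, 2] - 5) <= 1))

  # magnitude identity holds exactly
  set.seed(1)
  g <- sobel_gradient(matrix(rnorm(64), 8, 8))
  expect_equal(g$magnitude^2, g$gx^2 + g$gy^2)

  expect_error(sobel_gradient(matrix(0, 2, 5)), "3x3")
})

test_that("average gradient magnitude equals a loop-based oracle", {
  expect_equal(average_gradient_magnitude(matrix(3, 6, 6)), 0)
  # uniform-gradient ramp: interior magnitude is constant, mean equals it
  ramp <- matrix(rep(seq_len(8), each = 8), 8, 8)
  g <- sobel_gradient(ramp)$magnitude
  expect_equal(average_gradient_magnitude(ramp),
               unname(g[4, 4]))
  set.seed(42)
  sl <- matrix(runif(64), 8, 8)
  expect_equal(average_gradient_magnitude(sl), avg_gradient_oracle(sl),
               tolerance = 1e-12)
})

test_that("LoG kernel has the analytic center value and zero DC", {
  for (s in c(1, 2, 4)) {
    k <- log_kernel(s, dc_correct = FALSE)
    r <- (nrow(k) - 1) / 2
    expect_equal(k[r + 1, r + 1], 1 / (pi * s^4))
  }
  expect_equal(sum(log_kernel(4)), 0, tolerance = 1e-15)
  # constant slice: response is zero within the DC residual bound
  expect_lt(max(abs(log_response(matrix(7, 40, 40), 4))), 1e-6)
  expect_error(log_kernel(-1), "positive")
  expect_error(log_response(matrix(0, 10, 10), 0), "positive")
})

test_that("LoG response changes sign across a bright disk rim", {
  d <- disk_image(32, 10)
  resp <- log_response(d, 1.5)
  mid <- 16.5
  rr <- sqrt(outer((1:32 - mid)^2, (1:32 - mid)^2, "+"))
  # printed kernel is positive at the center, so the response is positive
  # inside the bright disk and negative just outside
  expect_gt(mean(resp[rr < 7]), 0)
  expect_lt(mean(resp[rr > 12 & rr < 15]), 0)
})

test_that("LoG zero-crossing edges ring the disk rim and degrade with sigma", {
  expect_false(any(log_edges(matrix(3, 20, 20), 2)))
  d <- disk_image(64, 10)
  e <- log_edges(d, 1.5)
  w <- which(e, arr.ind = TRUE)
  rim_err <- abs(sqrt((w[, 1] - 32.5)^2 + (w[, 2] - 32.5)^2) - 10)
  expect_gt(nrow(w), 20)
  expect_lt(max(rim_err), 1)
  # ring closure: the edge set has a single 8-connected component
  expect_equal(max(kneeseg:::cpp_label_components(unclass(e), 8L)), 1L)
  # kernel comparable to the disk: localization degrades markedly
  e_big <- log_edges(d, 8)
  w <- which(e_big, arr.ind = TRUE)
  rim_err_big <- abs(sqrt((w[, 1] - 32.5)^2 + (w[, 2] - 32.5)^2) - 10)
  expect_gt(mean(rim_err_big), 5 * mean(rim_err))
})

test_that("Canny parameters are validated", {
  expect_error(canny_params(low = 0.9, high = 0.1), "low <= high")
  expect_error(canny_params(sigma = 0), "positive")
  expect_error(canny_params(low = -0.1), "low <= high")
  p <- canny_params()
  expect_equal(c(p$sigma, p$low, p$high), c(2, 0.10, 0.90))
})

test_that("Canny localizes a step to one thin line", {
  expect_false(any(canny_edges(matrix(3, 30, 30))))
  sl <- matrix(0, 40, 40); sl[, 21:40] <- 1
  e <- canny_edges(sl, canny_params(2, 0.10, 0.90))
  w <- which(e, arr.ind = TRUE)
  # one edge pixel per row, within +-1 pixel of the step at 20.5
  expect_equal(nrow(w), 40)
  expect_equal(sort(unique(w[, 1])), 1:40)
  expect_true(all(w[, 2] %in% c(20, 21)))
})

test_that("larger Canny smoothing suppresses impulse noise", {
  set.seed(3)
  sl <- matrix(0, 60, 60); sl[, 31:60] <- 1
  idx <- cbind(sample(1:60, 12), sample(c(1:24, 37:60), 12))
  sl[idx] <- sl[idx] + 3
  off_edge <- function(e) sum(e & col(e) %in% c(1:27, 34:60))
  n_small <- off_edge(canny_edges(sl, canny_params(0.5, 0.1, 0.9)))
  n_big <- off_edge(canny_edges(sl, canny_params(2, 0.1, 0.9)))
  expect_lt(n_big, n_small)
})

test_that("edge maps obey intensity invariances", {
  sl <- annulus_slice(48, 15, 9)
  for (fun in list(function(x) sobel_edges(x),
                   function(x) log_edges(x, 2),
                   function(x) canny_edges(x))) {
    e0 <- fun(sl)
    expect_equal(unclass(fun(sl + 137)), unclass(e0))   # shift invariance
    expect_equal(unclass(fun(sl * 2.5)), unclass(e0))   # relative thresholds
  }
  # Sobel and LoG responses scale linearly
  expect_equal(sobel_gradient(sl * 3)$magnitude,
               3 * sobel_gradient(sl)$magnitude)
  expect_equal(log_response(sl * 3, 2), 3 * log_response(sl, 2))
})

test_that("edge-length density matches the flood-fill oracle", {
  e <- matrix(FALSE, 8, 8)
  expect_equal(edge_length_density(e), matrix(0, 8, 8))
  # one component: density 1 on every edge pixel
  e[2, 2:7] <- TRUE
  d <- edge_length_density(e)
  expect_true(all(d[e] == 1))
  # components of 10 and 5 pixels: densities 1 and 0.5
  e <- matrix(FALSE, 12, 12)
  e[2, 1:10] <- TRUE
  e[8, 1:5] <- TRUE
  d <- edge_length_density(e)
  expect_equal(unique(d[2, 1:10]), 1)
  expect_equal(unique(d[8, 1:5]), 0.5)
  # randomized maps vs the oracle
  set.seed(99)
  for (i in 1:12) {
    e <- matrix(runif(16 * 16) < 0.3, 16, 16)
    expect_equal(edge_length_density(e), edge_density_oracle(e))
  }
  # optional density filter drops short components
  e <- matrix(FALSE, 12, 12); e[2, 1:10] <- TRUE; e[8, 1:3] <- TRUE
  f <- filter_edges_by_density(edge_map(e, "canny"), 0.5)
  expect_true(all(f[2, 1:10]) && !any(f[8, ]))
})

test_that("segment_slice traces bone contours in mm coordinates", {
  # annulus: exactly one outer contour within one voxel of the outer rim
  sl <- annulus_slice(64, r_out = 20, r_in = 12)
  for (m in c("sobel", "log", "canny")) {
    cs <- segment_slice(sl, m, spacing = c(0.5, 0.5), min_area = 30)
    expect_length(cs$contours, 1)
    p <- cs$contours[[1]]
    r <- sqrt((p[, 1] - 0.5 * 31.5)^2 + (p[, 2] - 0.5 * 31.5)^2)
    expect_lt(max(abs(r - 0.5 * 20)), 0.5)  # 1 voxel = 0.5 mm
  }
  # empty slice: empty contour set with a warning
  expect_warning(cs <- segment_slice(matrix(40, 48, 48), "canny"),
                 "empty contour")
  expect_length(cs$contours, 0)
  # two separated bones: two outer contours
  two <- annulus_slice(96, 14, 8, cx = 26, cy = 48) +
    annulus_slice(96, 11, 6, cx = 70, cy = 48) - 40
  cs <- segment_slice(two, "canny", spacing = c(1, 1), min_area = 30)
  expect_length(cs$contours, 2)
})

test_that("contours round-trip through CSV", {
  sl <- annulus_slice(64, 20, 12)
  cs <- segment_slice(sl, "canny", spacing = c(0.5, 0.5), z = 3)
  stack <- contour_stack(list(cs), slice_spacing = 1)
  tb <- contours_to_tibble(stack)
  expect_named(tb, c("slice_z", "contour_id", "vertex_index", "x_mm", "y_mm"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_contours(stack, path)
  back <- read_contours(path, slice_spacing = 1)
  expect_equal(length(back$slices), 1)
  expect_equal(back$slices[[1]]$contours[[1]], cs$contours[[1]],
               ignore_attr = TRUE, tolerance = 1e-12)
})
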