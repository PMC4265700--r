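test_that("rasterization fills contours by the even-odd rule", {
  sq <- matrix(c(0, 0, 10, 0, 10, 10, 0, 10), ncol = 2, byrow = TRUE)
  stack <- contour_stack(list(contour_set(list(sq), z = 0)), slice_spacing = 1)
  vol <- rasterize_contours(stack, origin = c(0.5, 0.5, 0),
                            spacing = c(1, 1, 1), dim = c(12, 12, 3))
  expect_equal(sum(vol$mask), 100)  # 10 x 10 mm square at 1 mm spacing

  # circle: inside count within 5% of pi r^2 / spacing^2
  th <- seq(0, 2 * pi, length.out = 200)[-200]
  circ <- cbind(10 + 7 * cos(th), 10 + 7 * sin(th))
  stack <- contour_stack(list(contour_set(list(circ), z = 0)),
                         slice_spacing = 1)
  vol <- rasterize_contours(stack, spacing = c(0.5, 0.5, 1))
  expect_equal(sum(vol$mask), pi * 7^2 / 0.25, tolerance = 0.05)

  # inner contour cuts a hole (even-odd)
  inner <- cbind(10 + 3 * cos(th), 10 + 3 * sin(th))
  stack <- contour_stack(list(contour_set(list(circ, inner), z = 0)),
                         slice_spacing = 1)
  vol <- rasterize_contours(stack, spacing = c(0.5, 0.5, 1))
  expect_equal(sum(vol$mask), pi * (7^2 - 3^2) / 0.25, tolerance = 0.05)

  # empty stack -> all-false volume
  stack <- contour_stack(list(contour_set(list(), z = 0)), slice_spacing = 1)
  expect_false(any(rasterize_contours(stack)$mask))

  # contour outside an explicit grid -> extent error
  stack <- contour_stack(list(contour_set(list(sq), z = 0)), slice_spacing = 1)
  expect_error(rasterize_contours(stack, origin = c(0, 0, 0),
                                  spacing = c(1, 1, 1), dim = c(5, 5, 3)),
               "outside")
})

test_that("shape-based interpolation morphs between cross-sections", {
  v <- array(FALSE, c(21, 21, 3))
  v[8:14, 8:14, ] <- TRUE
  expect_identical(interpolate_slices(v, 1), v)
  expect_error(interpolate_slices(v, 0), "integer")

  # identical neighbouring slices reproduce themselves in between
  vi <- interpolate_slices(v, 2)
  expect_equal(dim(vi)[3], 5)
  for (k in 1:5) expect_equal(vi[, , k], v[, , 1])

  # concentric disks: inserted slice radius near the mean radius
  v <- array(FALSE, c(41, 41, 2))
  v[, , 1] <- disk_image(41, 8) > 0
  v[, , 2] <- disk_image(41, 14) > 0
  vi <- interpolate_slices(v, 2)
  r_mid <- sqrt(sum(vi[, , 2]) / pi)
  expect_lt(abs(r_mid - 11), 1)
  # monotone: inserted area between neighbours
  expect_true(sum(v[, , 1]) <= sum(vi[, , 2]) &&
                sum(vi[, , 2]) <= sum(v[, , 2]))
})

test_that("isosurface extraction reproduces analytic solids", {
  m <- sphere_mesh(10)
  r <- sqrt(rowSums(m$vertices^2))
  expect_true(all(r >= 9 & r <= 11))
  expect_true(is_watertight(m))
  expect_equal(euler_characteristic(m), 2)
  expect_equal(mesh_area(m), 4 * pi * 100, tolerance = 0.1)
  expect_equal(mesh_volume(m), 4 / 3 * pi * 1000, tolerance = 0.05)

  # box volume by divergence theorem within 5%
  v <- array(FALSE, c(20, 16, 12))
  v[4:16, 4:12, 4:8] <- TRUE
  bm <- extract_surface(v)
  expect_true(is_watertight(bm))
  expect_equal(mesh_volume(bm), 13 * 9 * 5, tolerance = 0.05)

  expect_error(extract_surface(array(FALSE, c(5, 5, 5))), "no crossing")
  expect_error(extract_surface(array(TRUE, c(5, 5, 5))), "no crossing")
})

test_that("rasterize -> extract -> inside test closes the loop", {
  th <- seq(0, 2 * pi, length.out = 120)[-120]
  circ <- cbind(15 + 9 * cos(th), 15 + 9 * sin(th))
  sets <- lapply(0:6, function(z) contour_set(list(circ), z = z))
  stack <- contour_stack(sets, slice_spacing = 1)
  vol <- rasterize_contours(stack, spacing = c(1, 1, 1))
  mesh <- extract_surface(vol)
  expect_true(is_watertight(mesh))
  # enclosed volume agrees with the voxel count up to a boundary band
  expect_equal(mesh_volume(mesh), sum(vol$mask), tolerance = 0.15)
  # voxel centers well inside are inside the mesh (signed distance < 0)
  idx <- which(vol$mask, arr.ind = TRUE)
  pts <- sweep(sweep(idx - 1, 2, vol$spacing, "*"), 2, vol$origin, "+")
  sd <- kneeseg:::cpp_signed_distance(pts, mesh$vertices, mesh$faces)
  expect_gt(mean(sd$signed_distance < 0.5), 0.95)
})

test_that("surface_mesh validates its inputs", {
  expect_error(surface_mesh(matrix(0, 3, 2), matrix(1L, 1, 3)), "n x 3")
  expect_error(surface_mesh(matrix(0, 3, 3), matrix(c(1L, 2L, 4L), 1)),
               "out of range")
})
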