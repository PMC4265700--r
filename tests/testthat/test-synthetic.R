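test_that("phantom generation is deterministic and validates geometry", {
  spec <- small_phantom_spec(seed = 4)
  a <- generate_phantom(spec)
  b <- generate_phantom(spec)
  expect_identical(a$volume$voxels, b$volume$voxels)
  # a different seed changes the noise
  c <- generate_phantom(small_phantom_spec(seed = 5))
  expect_false(identical(a$volume$voxels, c$volume$voxels))
  # the generator leaves the global RNG state alone
  set.seed(123); before <- .Random.seed
  generate_phantom(spec)
  expect_identical(.Random.seed, before)

  too_big <- phantom_spec(bones = list(list(type = "tube", center = c(5, 5),
                                            radius = 10, thickness = 2,
                                            zlim = c(0, 10))),
                          dim = c(24, 24, 12), spacing = c(0.5, 0.5, 1))
  expect_error(generate_phantom(too_big), "outside")
  expect_error(phantom_spec(bones = list(list(type = "tube", center = c(0, 0),
                                              radius = 3, thickness = 4,
                                              zlim = c(0, 5)))),
               "thickness")
  expect_error(phantom_spec(bones = list(list(type = "blob"))), "unknown")
})

test_that("noise-free unblurred phantoms take exactly the four levels", {
  spec <- phantom_spec(bones = list(list(type = "tube", center = c(14, 14),
                                         radius = 10, thickness = 4,
                                         zlim = c(3, 13))),
                       dim = c(56, 56, 16), spacing = c(0.5, 0.5, 1),
                       soft_zlim = c(1, 15), blur_sigma = 0, noise_sd = 0)
  ph <- generate_phantom(spec)
  expect_setequal(unique(as.vector(ph$volume$voxels)),
                  c(-100, 40, 300, 1200))
})

test_that("ground-truth meshes lie on the analytic surfaces", {
  ph <- generate_phantom(small_phantom_spec())
  V <- ph$mesh$vertices
  r <- sqrt((V[, 1] - 14)^2 + (V[, 2] - 14)^2)
  # every tube vertex is exactly at the outer radius (caps are fans over rim
  # vertices) or on a cap plane
  on_side <- abs(r - 10) < 0.1
  on_cap <- V[, 3] %in% c(3, 13)
  expect_true(all(on_side | on_cap))
  expect_true(all(abs(r[!on_cap] - 10) < 0.1))
  expect_true(is_watertight(ph$mesh))
  # inside test agrees with the mesh on probe points
  inside <- ph$inside(rbind(c(14, 14, 8), c(14 + 9.9, 14, 8),
                            c(14, 14, 2.5), c(25, 25, 8)))
  expect_equal(inside, c(TRUE, TRUE, FALSE, FALSE))

  sp <- phantom_spec(bones = list(list(type = "sphere", center = c(10, 10, 8),
                                       radius = 6, thickness = 2)),
                     dim = c(40, 40, 16), spacing = c(0.5, 0.5, 1))
  m <- generate_phantom(sp)$mesh
  d <- sqrt(rowSums(sweep(m$vertices, 2, c(10, 10, 8))^2))
  expect_true(all(abs(d - 6) < 1e-9))
  expect_true(is_watertight(m))
})

test_that("transformed clouds carry their exact transform", {
  mesh <- sphere_mesh(5, half = 7)
  cl <- generate_transformed_cloud(mesh)
  expect_equal(cl$points, mesh$vertices)
  expect_equal(cl$transform$rotation, diag(3))
  cl <- generate_transformed_cloud(mesh, angles = c(0, 0, 30),
                                   translation = c(1, 2, 3))
  expect_equal(cl$points, apply_transform(cl$transform, mesh$vertices))
  # seeded noise is reproducible
  n1 <- generate_transformed_cloud(mesh, noise_sigma = 0.5, seed = 9)
  n2 <- generate_transformed_cloud(mesh, noise_sigma = 0.5, seed = 9)
  expect_identical(n1$points, n2$points)
})

test_that("synthetic stress-strain curves honour the model", {
  p <- ogden_parameters(1.5, 8)
  cur <- generate_stress_strain(p, n = 20)
  expect_equal(cur$stress_mpa[1], 0)  # sigma(1) = 0 exactly
  expect_true(all(diff(cur$stress_mpa) > 0))  # stiffening params
  expect_equal(cur$stress_mpa, uniaxial_stress(cur$stretch, p))
  n1 <- generate_stress_strain(p, noise_sigma = 0.1, seed = 2)
  n2 <- generate_stress_strain(p, noise_sigma = 0.1, seed = 2)
  expect_identical(n1$stress_mpa, n2$stress_mpa)
})

test_that("synthetic angle tables have closed-form error rates", {
  gen <- generate_angle_tables(list("Method 2" = 0, "Method 3" = c(1, 1, 1, 1)))
  expect_equal(unname(gen$eta), c(0, 4))
  set.seed(21)
  off <- list("Method 2" = rnorm(4), "Method 3" = rnorm(4))
  gen <- generate_angle_tables(off)
  rep_tab <- gen$table
  for (m in names(off)) {
    got <- error_rate(angle_table_series(rep_tab, "Method 1", "von_mises"),
                      angle_table_series(rep_tab, m, "von_mises"))
    expect_equal(got, sum(abs(off[[m]])))
    expect_equal(got, gen$eta[[m]])
  }
})
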