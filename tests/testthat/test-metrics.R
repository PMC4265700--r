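test_that("the per-angle error rate is the sum of absolute differences", {
  ref <- angle_series(c(7.447, 6.356, 5.67, 6.371))
  expect_equal(error_rate(ref, ref), 0)
  expect_equal(error_rate(ref, c(8.06, 6.694, 5.858, 6.082)), 1.428)
  expect_equal(error_rate(c(9.878, 6.43, 6.324, 6.354),
                          c(9.153, 8.996, 9.256, 8.885)), 8.754)
  expect_equal(error_rate(c(11.391, 7.278, 5.235, 3.914),
                          c(20.319, 8.87, 5.185, 3.728)), 10.756)
  # variants for sensitivity analysis
  expect_equal(error_rate(ref, c(8.06, 6.694, 5.858, 6.082),
                          variant = "mean_abs"), 1.428 / 4)
  d <- c(8.06, 6.694, 5.858, 6.082) - ref$value
  expect_equal(error_rate(ref, c(8.06, 6.694, 5.858, 6.082),
                          variant = "rms"), sqrt(mean(d^2)))
  expect_error(error_rate(ref, angle_series(1:3, angles = c(0, 45, 90))),
               "same angle")
})

test_that("the error rate behaves as an L1 metric on aligned series", {
  set.seed(13)
  for (i in 1:10) {
    a <- angle_series(rnorm(4, 8)); b <- angle_series(rnorm(4, 8))
    cc <- angle_series(rnorm(4, 8))
    expect_gte(error_rate(a, b), 0)
    expect_equal(error_rate(a, b), error_rate(b, a))
    expect_lte(error_rate(a, cc), error_rate(a, b) + error_rate(b, cc) + 1e-12)
    # shift invariance and positive homogeneity
    sh <- angle_series(a$value + 3.7); bh <- angle_series(b$value + 3.7)
    expect_equal(error_rate(sh, bh), error_rate(a, b))
    expect_equal(error_rate(angle_series(2 * a$value),
                            angle_series(2 * b$value)),
                 2 * error_rate(a, b))
  }
  expect_equal(error_rate(angle_series(c(1, 2, 3, 4)),
                          angle_series(c(1, 2, 3, 4))), 0)
})

test_that("angle tables parse, validate and round-trip", {
  tab <- read_angle_table(table1_path())
  expect_equal(sort(unique(tab$method)), paste("Method", 1:4))
  expect_equal(length(unique(tab$quantity)), 4)
  expect_equal(nrow(tab), 64)
  s <- angle_table_series(tab, "Method 1", "von_mises")
  expect_equal(s$value, c(7.447, 6.356, 5.67, 6.371))

  path <- withr::local_tempfile(fileext = ".csv")
  write_angle_table(tab, path)
  expect_equal(read_angle_table(path)$value, tab$value)

  empty <- withr::local_tempfile(fileext = ".csv")
  file.create(empty)
  expect_error(read_angle_table(empty), "parse error|columns")
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("method,quantity,angle_deg,value",
               "M1,q,0,1", "M1,q,45,2", "M2,q,0,1"), bad)
  expect_error(read_angle_table(bad), "all angles")
  nonnum <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("method,quantity,angle_deg,value",
               "M1,q,0,1", "M1,q,45,oops"), nonnum)
  expect_error(read_angle_table(nonnum), "missing or non-numeric")
})

test_that("build_report reproduces the published ranking", {
  tab <- read_angle_table(table1_path())
  morph <- c("Method 2" = 0.0388, "Method 3" = 0.1081, "Method 4" = 0.0117)
  rep <- build_report(tab, reference = "Method 1", morphological = morph)
  # all twelve error rates at the printed precision
  eta <- rep$eta
  get <- function(m, q) eta$eta[eta$method == m & eta$quantity == q]
  expect_equal(get("Method 2", "von_mises"), 1.428, tolerance = 5e-4)
  expect_equal(get("Method 3", "von_mises"), 1.439, tolerance = 5e-4)
  expect_equal(get("Method 4", "von_mises"), 1.152, tolerance = 5e-4)
  expect_equal(get("Method 3", "reaction_force"), 2.103, tolerance = 5e-4)
  # Method 4 wins 3 of the 5 experiments; ranking M4 > M3 > M2
  expect_equal(rep$ranking$method, paste("Method", c(4, 3, 2)))
  expect_equal(rep$ranking$wins, c(3, 2, 0))
  win4 <- sort(rep$winners$quantity[rep$winners$method == "Method 4"])
  expect_equal(win4, c("contact_femur", "morphology", "von_mises"))
  expect_s3_class(autoplot(rep), "ggplot")
  expect_equal(glance(rep)$best_method, "Method 4")
})

test_that("build_report handles ties and unanimity deterministically", {
  gen <- generate_angle_tables(list("A" = c(1, 0, 0, 0), "B" = c(0, -1, 0, 0)))
  rep <- build_report(gen$table, reference = "Method 1")
  expect_equal(nrow(rep$winners), 2)  # equal eta: tie reported explicitly
  expect_equal(rep$ranking$wins, c(1, 1))
  expect_equal(rep$ranking$method, c("A", "B"))  # lexicographic tie-break

  gen <- generate_angle_tables(list("A" = 0.1, "B" = 2))
  rep <- build_report(gen$table, reference = "Method 1")
  expect_equal(rep$ranking$method[1], "A")
  expect_equal(rep$ranking$wins, c(1, 0))
  expect_error(build_report(gen$table, reference = "nope"), "not present")
})

test_that("report JSON serialises the eta table and ranking", {
  tab <- read_angle_table(table1_path())
  rep <- build_report(tab, reference = "Method 1")
  path <- withr::local_tempfile(fileext = ".json")
  write_report_json(rep, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$ranking$method[1], "Method 4")
  expect_equal(nrow(back$eta), 12)
})
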