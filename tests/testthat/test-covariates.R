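test_that("climate anomaly is cellwise future minus baseline with mask propagation", {
  base <- env_grid(matrix(c(25, 24, NA, 22), 2, 2), 0, 2, 1, "MAT", "degC")
  fut <- env_grid(matrix(c(26.5, 24, 30, 23), 2, 2), 0, 2, 1, "MAT_future")
  d <- climate_anomaly(fut, base, name = "dMAT")
  expect_equal(d$values[1, 1], 1.5)
  expect_equal(d$values[2, 1], 0)
  expect_true(is.na(d$values[1, 2]))  # baseline nodata propagates
  # identity: anomaly of a layer with itself is zero on the valid mask
  z <- climate_anomaly(base, base)
  expect_true(all(z$values[!is.na(base$values)] == 0))
  # misregistration is an error
  shifted <- env_grid(fut$values, 0.5, 2, 1)
  expect_error(climate_anomaly(shifted, base), "co-registered",
               class = "grid_error")
})

test_that("focal fill matches a brute-force window mean and never touches valid cells", {
  # no gaps: bit-identical return
  full <- env_grid(matrix(rnorm(30), 5, 6), 0, 5, 1)
  expect_identical(focal_fill(full, window = 3)$values, full$values)

  # constant neighborhood fills with the constant
  const <- env_grid(matrix(4.0, 21, 21), 0, 21, 1)
  const$values[11, 11] <- NA
  expect_equal(focal_fill(const, window = 19)$values[11, 11], 4.0)

  # randomized fixtures against an exhaustive loop oracle
  withr::with_seed(5, {
    for (rep in 1:5) {
      v <- matrix(rnorm(11 * 13), 11, 13)
      v[sample(length(v), 25)] <- NA
      g <- env_grid(v, 0, 11, 1)
      for (win in c(3, 5)) {
        filled <- focal_fill(g, window = win)
        half <- (win - 1) / 2
        for (i in 1:11) for (j in 1:13) {
          if (is.na(v[i, j])) {
            block <- v[max(1, i - half):min(11, i + half),
                       max(1, j - half):min(13, j + half)]
            expected <- mean(block, na.rm = TRUE)
            if (is.finite(expected)) {
              expect_equal(filled$values[i, j], expected)
            } else {
              expect_true(is.na(filled$values[i, j]))
            }
          } else {
            expect_identical(filled$values[i, j], v[i, j])
          }
        }
        # fill never reduces the number of valid cells
        expect_gte(sum(!is.na(filled$values)), sum(!is.na(v)))
      }
    }
  })

  expect_error(focal_fill(full, window = 4), "odd",
               class = "validation_error")
})

test_that("single-pass fill does not cascade freshly filled values", {
  # a 1 x 5 strip: values 1, NA, NA, NA, NA with window 3; only the first
  # gap has a valid neighbor, so exactly one cell is filled per pass
  g <- env_grid(matrix(c(1, NA, NA, NA, NA), 1, 5), 0, 1, 1)
  one <- focal_fill(g, window = 3)
  expect_equal(one$values[1, ], c(1, 1, NA, NA, NA))
  two <- focal_fill(g, window = 3, passes = 2)
  expect_equal(two$values[1, ], c(1, 1, 1, NA, NA))
})

test_that("point extraction matches floor-index arithmetic and flags outsiders", {
  stack <- tiny_stack()
  g <- stack_geometry(stack)
  # a cell center returns that cell's value in every layer
  pt <- tibble::tibble(longitude = 3.5, latitude = 2.5)
  got <- extract_at_points(stack, pt)
  expect_equal(got$alpha, stack$layers$alpha$values[3, 4])
  expect_equal(got$beta, stack$layers$beta$values[3, 4])
  expect_false(got$outside)

  # out-of-extent point: all-missing row, flagged, order preserved
  pts <- tibble::tibble(longitude = c(3.5, 99), latitude = c(2.5, 0))
  got2 <- extract_at_points(stack, pts)
  expect_equal(got2$outside, c(FALSE, TRUE))
  expect_true(is.na(got2$alpha[2]) && is.na(got2$beta[2]))

  # 20 random points against the index oracle
  withr::with_seed(9, {
    lon <- runif(20, 0, 12); lat <- runif(20, -5, 5)
    got3 <- extract_at_points(stack, tibble::tibble(longitude = lon,
                                                    latitude = lat))
    for (k in 1:20) {
      col <- floor((lon[k] - g$xmin) / g$cellsize) + 1
      row <- floor((g$ymax - lat[k]) / g$cellsize) + 1
      expect_equal(got3$alpha[k], stack$layers$alpha$values[row, col])
    }
  })

  expect_error(extract_at_points(structure(list(layers = list()),
                                           class = "env_stack"), pt),
               class = "stack_error")
})

test_that("background sampling is reproducible, in-domain, and unbiased", {
  cfg <- small_syncfg()
  stack <- gen_stack(cfg)
  a <- sample_background(stack, n = 500, seed = 3)
  b <- sample_background(stack, n = 500, seed = 3)
  expect_identical(a, b)
  expect_false(identical(a, sample_background(stack, n = 500, seed = 4)))

  # all sampled cells lie in the domain mask
  expect_true(all(stack$domain_mask[cbind(a$cell_row, a$cell_col)]))
  # distinct cells (without replacement)
  expect_equal(nrow(dplyr::distinct(a, cell_row, cell_col)), 500)

  # a domain with exactly n cells returns every cell once
  small <- env_stack(list(z = env_grid(matrix(1.0, 4, 5), 0, 4, 1)))
  expect_warning(all_cells <- sample_background(small, n = 21, seed = 1),
                 "returning all")
  expect_equal(nrow(sample_background(small, n = 20, seed = 1)), 20)
  expect_equal(nrow(all_cells), 20)

  # sample mean within 3 standard errors of the domain mean
  big <- sample_background(stack, n = 2000, seed = 5)
  for (nm in c("MAT", "MAP", "LAI")) {
    v <- stack$layers[[nm]]$values[stack$domain_mask]
    se <- stats::sd(v, na.rm = TRUE) / sqrt(2000)
    expect_lt(abs(mean(big[[nm]], na.rm = TRUE) - mean(v, na.rm = TRUE)),
              3 * se)
  }

  expect_error(sample_background(stack, n = 0), class = "validation_error")
})

test_that("ASCII grid and stack manifest round-trip preserves values and geometry", {
  g <- env_grid(matrix(c(1.5, NA, -2.25, 4e6, 0.1, 7), 2, 3), -10, 8, 0.5,
                "demo", "u")
  path <- withr::local_tempfile(fileext = ".asc")
  write_ascii_grid(g, path)
  back <- read_ascii_grid(path)
  expect_equal(back$values, g$values)
  expect_equal(back$xmin, g$xmin)
  expect_equal(back$ymax, g$ymax)
  expect_equal(back$cellsize, g$cellsize)

  dir <- withr::local_tempdir()
  stack <- tiny_stack()
  write_stack(stack, dir)
  back2 <- read_stack(dir)
  expect_equal(names(back2$layers), names(stack$layers))
  expect_equal(back2$layers$alpha$values, stack$layers$alpha$values)
  expect_equal(back2$domain_mask, stack$domain_mask)
})
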