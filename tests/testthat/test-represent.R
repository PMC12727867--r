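test_that("AUC equals the exhaustive pairwise-concordance oracle", {
  # perfect separation and all-tied degenerate cases
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1.0)
  expect_equal(roc_auc(rep(0.5, 6), c(1, 1, 1, 0, 0, 0)), 0.5)
  expect_equal(roc_auc(c(0.1, 0.2, 0.8, 0.9), c(1, 1, 0, 0)), 0.0)

  # every small input (sizes 2..12, discretized scores to force ties)
  withr::with_seed(31, {
    for (rep in 1:60) {
      n <- sample(2:12, 1)
      labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
      scores <- sample(seq(0, 1, 0.25), n, replace = TRUE)
      expect_equal(roc_auc(scores, labels), auc_pair_oracle(scores, labels))
    }
  })

  # independent library cross-check at moderate n
  withr::with_seed(32, {
    scores <- runif(200)
    labels <- rbinom(200, 1, plogis(3 * scores - 1.5))
    expect_equal(roc_auc(scores, labels),
                 as.numeric(pROC::auc(pROC::roc(labels, scores,
                                                quiet = TRUE,
                                                direction = "<"))),
                 tolerance = 1e-12)
  })

  expect_error(roc_auc(c(0.1, 0.2), c(1, 1)), class = "validation_error")
})

test_that("pseudo-absences match presence counts, avoid presence cells, reproduce", {
  cfg <- small_syncfg()
  stack <- gen_stack(cfg)
  lit <- gen_literature(stack, cfg)
  pres <- lit[1:100, ]
  pa <- make_pseudo_absences(stack, pres, seed = 5)
  expect_equal(sum(pa$label == 1), sum(pa$label == 0))
  expect_lte(nrow(pa), 200)
  expect_equal(nrow(pa), 2 * attr(pa, "n_presence"))

  # exclusion: no absence shares a cell with any presence
  g <- stack_geometry(stack)
  rc_all <- grid_rowcol(g, pa$longitude, pa$latitude)
  cell_id <- (rc_all$col - 1) * nrow(g$values) + rc_all$row
  pres_rc <- grid_rowcol(g, pres$longitude, pres$latitude)
  pres_cells <- unique((pres_rc$col - 1) * nrow(g$values) + pres_rc$row)
  expect_length(intersect(cell_id[pa$label == 0], pres_cells), 0)

  # determinism
  expect_identical(pa, make_pseudo_absences(stack, pres, seed = 5))
  expect_false(identical(pa$longitude,
                         make_pseudo_absences(stack, pres, seed = 6)$longitude))

  # domain smaller than the presence count is an error
  tiny <- env_stack(list(z = env_grid(matrix(1.0, 3, 3), 0, 3, 1)))
  expect_error(make_pseudo_absences(tiny, pres, seed = 1),
               class = "validation_error")
})

test_that("collinearity screen drops the right covariates at the 0.70 threshold", {
  withr::with_seed(41, {
    n <- 2000
    # mutually independent covariates are all retained
    ind <- tibble::tibble(a = rnorm(n), b = rnorm(n), c = rnorm(n))
    s0 <- collinearity_screen(ind, threshold = 0.70)
    expect_setequal(s0$retained, c("a", "b", "c"))

    # a duplicated covariate: exactly one of the pair is dropped
    dup <- dplyr::mutate(ind, a2 = a)
    s1 <- collinearity_screen(dup, threshold = 0.70)
    expect_length(s1$retained, 3)
    expect_length(intersect(c("a", "a2"), s1$retained), 1)

    # Cholesky-constructed pair at r = 0.69: both retained
    r <- 0.69
    z1 <- rnorm(n); z2 <- rnorm(n)
    x2 <- r * z1 + sqrt(1 - r^2) * z2
    near <- tibble::tibble(x1 = z1, x2 = x2, other = rnorm(n))
    # guard: the realized correlation is below the threshold
    stopifnot(abs(cor(near$x1, near$x2)) < 0.70)
    s2 <- collinearity_screen(near, threshold = 0.70)
    expect_setequal(s2$retained, c("x1", "x2", "other"))

    # the same construction at r = 0.85 drops one member
    x3 <- 0.85 * z1 + sqrt(1 - 0.85^2) * z2
    far <- tibble::tibble(x1 = z1, x3 = x3, other = rnorm(n))
    s3 <- collinearity_screen(far, threshold = 0.70)
    expect_length(s3$retained, 2)
    expect_true("other" %in% s3$retained)

    # constant covariate: dropped with a warning, not an error
    cst <- dplyr::mutate(ind, flat = 1)
    expect_warning(s4 <- collinearity_screen(cst, threshold = 0.70),
                   "constant")
    expect_false("flat" %in% s4$retained)
  })
})

test_that("ensemble separates separable classes and reproduces under a fixed seed", {
  withr::with_seed(51, {
    n <- 400
    x1 <- rnorm(n); x2 <- rnorm(n)
    tab <- tibble::tibble(x1 = x1, x2 = x2,
                          label = as.integer(x1 + 0.2 * x2 > 0))
  })
  model <- fit_ensemble(tab, covariates = c("x1", "x2"),
                        config = fast_model(), seed = 9)
  p <- predict_ensemble(model, tab)
  # each member separates the training classes nearly perfectly
  expect_gte(roc_auc(p$p_gam, tab$label), 0.99)
  expect_gte(roc_auc(p$p_rf, tab$label), 0.99)
  expect_gte(roc_auc(p$p_gbt, tab$label), 0.99)

  # median is bounded by member extremes and equals the sort-middle oracle
  m <- as.matrix(p[c("p_gam", "p_rf", "p_gbt")])
  expect_true(all(p$p_median >= apply(m, 1, min) - 1e-12))
  expect_true(all(p$p_median <= apply(m, 1, max) + 1e-12))
  oracle <- apply(m, 1, function(v) sort(v)[2])
  expect_equal(p$p_median, oracle)
  expect_true(all(m >= 0 & m <= 1))

  # determinism: refit with the same seed, identical probe predictions
  model2 <- fit_ensemble(tab, covariates = c("x1", "x2"),
                         config = fast_model(), seed = 9)
  expect_equal(predict_ensemble(model2, tab), p)

  # contract errors
  one_class <- dplyr::mutate(tab, label = 1L)
  expect_error(fit_ensemble(one_class, covariates = c("x1", "x2")),
               class = "validation_error")
  expect_error(fit_ensemble(tab[1:2, ], covariates = c("x1", "x2")),
               class = "validation_error")
  expect_error(predict_ensemble(model, tibble::tibble(x1 = 1)),
               class = "predict_error")
})

test_that("coverage area uses strict > and is monotone in the threshold", {
  ones <- env_grid(matrix(1.0, 1, 10), 0, 0.5, 1)  # one equatorial row
  expect_equal(coverage_area(ones, 0.5)$covered_fraction, 1.0)

  halves <- env_grid(matrix(0.5, 1, 10), 0, 0.5, 1)
  expect_equal(coverage_area(halves, 0.5)$covered_fraction, 0.0)

  # equal-area cells (single latitude row): half 0.6, half 0.4
  split <- env_grid(matrix(c(rep(0.6, 5), rep(0.4, 5)), 1, 10), 0, 0.5, 1)
  expect_equal(coverage_area(split, 0.5)$covered_fraction, 0.5)

  # monotone non-increasing in the threshold
  withr::with_seed(61, {
    rnd <- env_grid(matrix(runif(200), 10, 20), 0, 5, 0.5)
    fr <- sapply(seq(0, 1, 0.1),
                 function(t) coverage_area(rnd, t)$covered_fraction)
    expect_true(all(diff(fr) <= 1e-12))
  })

  expect_error(coverage_area(ones, 1.5), class = "validation_error")
})

test_that("cross-validation returns the requested permutations and detects signal", {
  withr::with_seed(71, {
    n <- 300
    x1 <- rnorm(n); x2 <- rnorm(n)
    sep <- tibble::tibble(x1 = x1, x2 = x2,
                          label = as.integer(x1 > 0))
  })
  cv <- cross_validate(sep, covariates = c("x1", "x2"),
                       config = fast_model(), n_perm = 5, seed = 3)
  expect_length(cv$auc_values, 5)
  expect_equal(cv$mean_auc, mean(cv$auc_values))
  expect_equal(cv$min_auc, min(cv$auc_values))
  expect_gte(cv$mean_auc, 0.95)

  # reproducibility under one seed
  cv2 <- cross_validate(sep, covariates = c("x1", "x2"),
                        config = fast_model(), n_perm = 5, seed = 3)
  expect_identical(cv$auc_values, cv2$auc_values)

  # a table too small for a stratified split errors out
  expect_error(cross_validate(sep[1:3, ], covariates = c("x1", "x2"),
                              n_perm = 2),
               class = "validation_error")

  # tidy/glance accessors are consistent with the raw list
  td <- generics::tidy(cv)
  expect_equal(nrow(td), 5)
  expect_equal(generics::glance(cv)$mean_auc, cv$mean_auc)
})

test_that("probability maps respect the domain mask and summarize coverage", {
  cfg <- small_syncfg()
  stack <- gen_stack(cfg)
  lit <- gen_literature(stack, cfg)
  pa <- make_pseudo_absences(stack, lit, seed = 2,
                             covariates = c("MAT", "MAP", "SOC"))
  model <- fit_ensemble(pa, covariates = c("MAT", "MAP", "SOC"),
                        config = fast_model(), seed = 2)
  mp <- predict_map(model, stack)
  vals <- mp$probability$values
  expect_true(all(vals[!is.na(vals)] >= 0 & vals[!is.na(vals)] <= 1))
  # cells outside the domain are nodata
  expect_true(all(is.na(vals[!stack$domain_mask])))
  cov <- coverage_area(mp$probability, 0.5)
  expect_equal(mp$covered_fraction, cov$covered_fraction)
  expect_equal(mp$covered_area_km2, cov$covered_area_km2)
})
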