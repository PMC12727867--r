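#' Ensemble hyperparameter configuration
#'
#' Defaults: penalized-spline additive model with automatic smoothness
#' selection (basis size `gam_k` per covariate), a 500-tree random forest
#' with default feature subsampling, and gradient-boosted trees with 1000
#' rounds, learning rate 0.01 and interaction depth 3. All fits are
#' single-threaded so results are reproducible.
#'
#' @param gam_k Spline basis size per smooth (`-1` = mgcv default).
#' @param rf_trees Random-forest tree count.
#' @param gbt_rounds,gbt_eta,gbt_depth Boosted-trees rounds, learning rate
#'   and maximum tree depth.
#' @return A list of hyperparameters.
#' @export
ensemble_config <- function(gam_k = -1, rf_trees = 500,
                            gbt_rounds = 1000, gbt_eta = 0.01,
                            gbt_depth = 3) {
  list(gam_k = gam_k, rf_trees = rf_trees, gbt_rounds = gbt_rounds,
       gbt_eta = gbt_eta, gbt_depth = gbt_depth)
}

#' Build a presence / pseudo-absence table
#'
#' Presences are the sampling locations; pseudo-absences are drawn uniformly
#' without replacement from domain cells, by default excluding any cell that
#' contains a presence, in numbers equal to the presences. Covariates are
#' attached by coordinate colocation; rows with any missing covariate are
#' removed and class parity is restored by down-sampling the larger class,
#' so equal numbers of presences and absences always enter the model.
#'
#' @param stack An [env_stack()].
#' @param presences Data frame with `longitude`, `latitude`.
#' @param seed Integer seed.
#' @param covariates Layer names to attach (default: all layers).
#' @param exclude_presence_cells Forbid absences in presence cells.
#' @return A `pa_table` tibble with `label` (1 presence / 0 absence),
#'   coordinates and covariates; attributes `n_presence`, `n_absence`.
#' @export
make_pseudo_absences <- function(stack, presences, seed = 1,
                                 covariates = names(stack$layers),
                                 exclude_presence_cells = TRUE) {
  g <- stack_geometry(stack)
  rc <- grid_rowcol(g, presences$longitude, presences$latitude)
  pres_cells <- unique((rc$col - 1L) * nrow(g$values) + rc$row)
  candidates <- which(stack$domain_mask)
  if (exclude_presence_cells) candidates <- setdiff(candidates, pres_cells)
  n_pres <- nrow(presences)
  if (length(candidates) < n_pres) {
    stop_tropirep("not enough absence candidate cells in the domain",
                  "validation_error")
  }
  picked <- withr::with_seed(derive_seed(seed, "absences"),
                             sample(candidates, n_pres))
  nr <- nrow(g$values)
  abs_pts <- tibble(
    longitude = grid_lon_centers(g)[((picked - 1) %/% nr) + 1],
    latitude = grid_lat_centers(g)[((picked - 1) %% nr) + 1]
  )
  pres_cov <- extract_at_points(stack, presences[c("longitude", "latitude")])
  abs_cov <- extract_at_points(stack, abs_pts)
  pres_cov <- pres_cov[c("longitude", "latitude", covariates)]
  abs_cov <- abs_cov[c("longitude", "latitude", covariates)]
  pres_cov$label <- 1L
  abs_cov$label <- 0L
  both <- bind_rows(pres_cov, abs_cov)
  complete <- complete.cases(both[covariates])
  both <- both[complete, , drop = FALSE]
  n1 <- sum(both$label == 1); n0 <- sum(both$label == 0)
  n_keep <- min(n1, n0)
  idx1 <- which(both$label == 1)
  idx0 <- which(both$label == 0)
  trim <- function(idx, k, tag) {
    if (length(idx) == k) return(idx)
    sort(withr::with_seed(derive_seed(seed, tag), sample(idx, k)))
  }
  both <- both[sort(c(trim(idx1, n_keep, "trim1"), trim(idx0, n_keep, "trim0"))), ]
  out <- both[c("longitude", "latitude", "label", covariates)]
  attr(out, "n_presence") <- n_keep
  attr(out, "n_absence") <- n_keep
  class(out) <- c("pa_table", class(out))
  out
}

#' Iterative pairwise-correlation screen of covariates
#'
#' Computes pairwise Pearson correlations; while any retained pair has
#' `|r| >= threshold`, the member of the worst pair with the larger mean
#' absolute correlation to all other retained covariates is dropped.
#' Constant covariates (undefined correlation) are dropped first with a
#' warning.
#'
#' @param data Data frame containing the covariates.
#' @param covariates Covariate column names (default: all numeric columns
#'   except `label`, `longitude`, `latitude`).
#' @param threshold Correlation threshold (default 0.70).
#' @return A `screen_report`: `retained`, `dropped` (with reasons), and the
#'   full correlation matrix.
#' @export
collinearity_screen <- function(data, covariates = NULL, threshold = 0.70) {
  if (is.null(covariates)) {
    covariates <- setdiff(names(data)[map_lgl(data, is.numeric)],
                          c("label", "longitude", "latitude",
                            "allocated_citations", "total_citations",
                            "cell_row", "cell_col"))
  }
  if (length(covariates) < 2) {
    stop_tropirep("need at least two covariates", "validation_error")
  }
  x <- data[covariates]
  dropped <- tibble(variable = character(), reason = character())
  const <- names(x)[map_lgl(x, function(v) stats::sd(v, na.rm = TRUE) == 0 ||
                              !is.finite(stats::sd(v, na.rm = TRUE)))]
  if (length(const) > 0) {
    warn(paste("dropping constant covariate(s):", paste(const, collapse = ", ")))
    dropped <- bind_rows(dropped,
                         tibble(variable = const, reason = "constant"))
    x <- x[setdiff(names(x), const)]
  }
  full_cor <- cor(x, use = "pairwise.complete.obs")
  retained <- names(x)
  repeat {
    cm <- abs(full_cor[retained, retained, drop = FALSE])
    diag(cm) <- 0
    if (length(retained) < 2 || max(cm) < threshold) break
    worst <- which(cm == max(cm), arr.ind = TRUE)[1, ]
    a <- retained[worst[1]]; b <- retained[worst[2]]
    mean_abs <- function(v) mean(cm[v, setdiff(retained, v)])
    drop_var <- if (mean_abs(a) >= mean_abs(b)) a else b
    dropped <- bind_rows(dropped, tibble(
      variable = drop_var,
      reason = sprintf("|r|=%.3f with %s", max(cm),
                       setdiff(c(a, b), drop_var))
    ))
    retained <- setdiff(retained, drop_var)
  }
  structure(list(retained = retained, dropped = dropped,
                 threshold = threshold, cor_matrix = full_cor),
            class = "screen_report")
}

#' @export
print.screen_report <- function(x, ...) {
  cat(sprintf("<screen_report> threshold %.2f: %d retained (%s)\n",
              x$threshold, length(x$retained),
              paste(x$retained, collapse = ", ")))
  if (nrow(x$dropped) > 0) {
    cat("  dropped:",
        paste(sprintf("%s [%s]", x$dropped$variable, x$dropped$reason),
              collapse = "; "), "\n")
  }
  invisible(x)
}

member_formula <- function(covariates, k) {
  as.formula(paste("label ~",
                   paste(sprintf("s(%s, k = %d)", covariates, k),
                         collapse = " + ")))
}

fit_members <- function(data, covariates, config, seed) {
  x <- as.matrix(data[covariates])
  y <- data$label
  k <- if (config$gam_k > 0) config$gam_k else 10
  gam_fit <- mgcv::bam(member_formula(covariates, k), data = data,
                       family = stats::binomial(), discrete = TRUE,
                       nthreads = 1)
  rf_fit <- ranger::ranger(
    x = data[covariates], y = factor(y, levels = c(0, 1)),
    num.trees = config$rf_trees, probability = TRUE,
    num.threads = 1, seed = derive_seed(seed, "rf")
  )
  gbt_fit <- xgboost::xgb.train(
    params = list(objective = "binary:logistic", eta = config$gbt_eta,
                  max_depth = config$gbt_depth, nthread = 1,
                  seed = derive_seed(seed, "gbt")),
    data = xgboost::xgb.DMatrix(x, label = y), nrounds = config$gbt_rounds,
    verbose = 0
  )
  list(gam = gam_fit, rf = rf_fit, gbt = gbt_fit)
}

#' Fit the presence/pseudo-absence ensemble
#'
#' Trains the three members — a binomial penalized-spline additive model, a
#' probability random forest, and gradient-boosted trees — on identical
#' rows of a presence/pseudo-absence table. Member probabilities are later
#' combined cellwise by their median ([predict_ensemble()]).
#'
#' @param table A `pa_table` (see [make_pseudo_absences()]) or any data
#'   frame with a 0/1 `label` column.
#' @param covariates Covariate names to use; these should already have
#'   passed [collinearity_screen()]. Defaults to the screen applied to
#'   `table`.
#' @param config An [ensemble_config()].
#' @param seed Integer seed driving the stochastic members.
#' @return A `repr_ensemble` with `members`, `covariates`, `config`,
#'   `screen`, and `seed`.
#' @export
fit_ensemble <- function(table, covariates = NULL,
                         config = ensemble_config(), seed = 1) {
  if (length(unique(table$label)) < 2) {
    stop_tropirep("both classes must be present to fit the ensemble",
                  "validation_error")
  }
  screen <- NULL
  if (is.null(covariates)) {
    screen <- collinearity_screen(table)
    covariates <- screen$retained
  }
  if (nrow(table) < length(covariates) + 1) {
    stop_tropirep("fewer rows than covariates + 1", "validation_error")
  }
  members <- fit_members(as.data.frame(table), covariates, config, seed)
  structure(
    list(members = members, covariates = covariates, config = config,
         screen = screen, seed = seed,
         n_presence = sum(table$label == 1),
         n_absence = sum(table$label == 0)),
    class = "repr_ensemble"
  )
}

#' @export
print.repr_ensemble <- function(x, ...) {
  cat(sprintf(
    "<repr_ensemble> GAM + RF(%d trees) + GBT(%d rounds) on %d covariates; %d presences / %d absences\n",
    x$config$rf_trees, x$config$gbt_rounds, length(x$covariates),
    x$n_presence, x$n_absence))
  invisible(x)
}

member_predictions <- function(model, newdata) {
  missing_cov <- setdiff(model$covariates, names(newdata))
  if (length(missing_cov) > 0) {
    stop_tropirep(paste("covariates absent from new data:",
                        paste(missing_cov, collapse = ", ")), "predict_error")
  }
  nd <- as.data.frame(newdata[model$covariates])
  x <- as.matrix(nd)
  tibble(
    p_gam = as.numeric(predict(model$members$gam, newdata = nd,
                               type = "response", discrete = FALSE)),
    p_rf = predict(model$members$rf, data = nd,
                   num.threads = 1)$predictions[, "1"],
    p_gbt = as.numeric(predict(model$members$gbt, xgboost::xgb.DMatrix(x)))
  )
}

#' Ensemble median probability for new rows
#'
#' Scores each row with all three members and returns the per-row member
#' probabilities and their median, the ensemble's representativeness
#' probability (bounded by the member minimum and maximum by construction).
#'
#' @param model A [fit_ensemble()] result.
#' @param newdata Data frame carrying the model covariates.
#' @return A tibble with `p_gam`, `p_rf`, `p_gbt`, `p_median`.
#' @export
predict_ensemble <- function(model, newdata) {
  p <- member_predictions(model, newdata)
  p$p_median <- apply(as.matrix(p), 1, median)
  p
}

#' Ensemble probability map over a covariate stack
#'
#' Predicts the ensemble median for every domain cell with complete
#' covariates (cells missing any covariate are nodata) and summarizes the
#' covered area above the decision threshold.
#'
#' @param model A [fit_ensemble()] result.
#' @param stack An [env_stack()].
#' @param threshold Probability above which a cell counts as covered.
#' @return A `repr_map`: `probability` ([env_grid()]), `covered_fraction`,
#'   `covered_area_km2`, `threshold`.
#' @export
predict_map <- function(model, stack, threshold = 0.5) {
  g <- stack_geometry(stack)
  cells <- which(stack$domain_mask)
  vals <- map(stack$layers[model$covariates], function(l) l$values[cells])
  tab <- as_tibble(vals)
  ok <- complete.cases(tab)
  prob <- matrix(NA_real_, nrow(g$values), ncol(g$values))
  if (any(ok)) {
    p <- predict_ensemble(model, tab[ok, , drop = FALSE])
    prob[cells[ok]] <- p$p_median
  }
  prob_grid <- env_grid(prob, g$xmin, g$ymax, g$cellsize,
                        name = "representativeness", units = "probability")
  cov <- coverage_area(prob_grid, threshold = threshold)
  structure(
    list(probability = prob_grid, threshold = threshold,
         covered_fraction = cov$covered_fraction,
         covered_area_km2 = cov$covered_area_km2),
    class = "repr_map"
  )
}

#' @export
print.repr_map <- function(x, ...) {
  cat(sprintf(
    "<repr_map> threshold %.2f: %.1f%% of domain covered (%.4g km^2)\n",
    x$threshold, 100 * x$covered_fraction, x$covered_area_km2))
  invisible(x)
}

#' @method autoplot repr_map
#' @export
autoplot.repr_map <- function(object, ...) {
  autoplot(object$probability) +
    labs(fill = "P(sampled)")
}

#' Covered area above a probability threshold
#'
#' Sums spherical cell areas where the probability strictly exceeds the
#' threshold; the fraction is relative to all valid (non-nodata) cells.
#'
#' @param probability An [env_grid()] of probabilities in `[0, 1]`.
#' @param threshold Decision threshold in `[0, 1]` (strict `>`).
#' @param mask Optional logical matrix restricting the evaluation.
#' @return One-row tibble: `covered_fraction`, `covered_area_km2`,
#'   `total_area_km2`, `threshold`.
#' @export
coverage_area <- function(probability, threshold = 0.5, mask = NULL) {
  if (threshold < 0 || threshold > 1) {
    stop_tropirep("`threshold` must be in [0, 1]", "validation_error")
  }
  valid <- !is.na(probability$values)
  if (!is.null(mask)) valid <- valid & mask
  areas <- cell_areas(probability)$values
  total <- sum(areas[valid])
  covered <- sum(areas[valid & !is.na(probability$values) &
                         probability$values > threshold])
  tibble(covered_fraction = if (total > 0) covered / total else 0,
         covered_area_km2 = covered, total_area_km2 = total,
         threshold = threshold)
}

#' Area under the ROC curve
#'
#' Probability that a randomly chosen positive outscores a randomly chosen
#' negative, counting ties as one half:
#' `(#concordant + 0.5 #tied) / (#pos * #neg)`, computed via mid-ranks.
#' Perfect separation gives 1; identical scores give 0.5.
#'
#' @param scores Numeric prediction scores.
#' @param labels 0/1 (or logical) class labels; both classes required.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels) | labels == 1)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) {
    stop_tropirep("both classes must be present to compute AUC",
                  "validation_error")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Repeated-split cross-validation of the ensemble
#'
#' Repeats, `n_perm` times: draw a random split with `train_frac` of each
#' class for training (stratified, so both classes appear in every
#' partition), fit the three-member ensemble on the training portion, score
#' the held-out rows with the ensemble median, and record the AUC.
#'
#' @param table A `pa_table` or data frame with a 0/1 `label`.
#' @param covariates Covariate names (default: collinearity screen).
#' @param config An [ensemble_config()].
#' @param n_perm Number of permutations (default 99).
#' @param train_frac Training fraction (default 0.7).
#' @param seed Integer seed.
#' @return A `repr_cv`: `auc_values` (length `n_perm`), `mean_auc`,
#'   `min_auc`, `max_auc`, and the run parameters.
#' @export
cross_validate <- function(table, covariates = NULL,
                           config = ensemble_config(), n_perm = 99,
                           train_frac = 0.7, seed = 1) {
  if (is.null(covariates)) {
    covariates <- collinearity_screen(table)$retained
  }
  idx1 <- which(table$label == 1)
  idx0 <- which(table$label == 0)
  n_tr1 <- round(train_frac * length(idx1))
  n_tr0 <- round(train_frac * length(idx0))
  if (n_tr1 < 1 || n_tr0 < 1 || n_tr1 >= length(idx1) || n_tr0 >= length(idx0)) {
    stop_tropirep("table too small for a stratified split at this fraction",
                  "validation_error")
  }
  aucs <- numeric(n_perm)
  df <- as.data.frame(table)
  for (i in seq_len(n_perm)) {
    split_seed <- derive_seed(seed, paste0("split", i))
    tr <- withr::with_seed(split_seed,
                           c(sample(idx1, n_tr1), sample(idx0, n_tr0)))
    te <- setdiff(seq_len(nrow(df)), tr)
    members <- fit_members(df[tr, , drop = FALSE], covariates, config,
                           derive_seed(seed, paste0("fit", i)))
    model <- structure(list(members = members, covariates = covariates),
                       class = "repr_ensemble")
    p <- predict_ensemble(model, df[te, , drop = FALSE])
    aucs[i] <- roc_auc(p$p_median, df$label[te])
  }
  structure(
    list(auc_values = aucs, mean_auc = mean(aucs), min_auc = min(aucs),
         max_auc = max(aucs), n_permutations = n_perm,
         train_fraction = train_frac, seed = seed,
         covariates = covariates),
    class = "repr_cv"
  )
}

#' @export
print.repr_cv <- function(x, ...) {
  cat(sprintf(
    "<repr_cv> %d permutations at %.0f/%.0f: AUC mean %.3f [%.3f, %.3f]\n",
    x$n_permutations, 100 * x$train_fraction, 100 * (1 - x$train_fraction),
    x$mean_auc, x$min_auc, x$max_auc))
  invisible(x)
}

#' @method tidy repr_cv
#' @export
tidy.repr_cv <- function(x, ...) {
  tibble(permutation = seq_along(x$auc_values), auc = x$auc_values)
}

#' @method glance repr_cv
#' @export
glance.repr_cv <- function(x, ...) {
  tibble(n_permutations = x$n_permutations, mean_auc = x$mean_auc,
         min_auc = x$min_auc, max_auc = x$max_auc,
         train_fraction = x$train_fraction)
}

#' @method autoplot repr_cv
#' @export
autoplot.repr_cv <- function(object, ...) {
  ggplot(tidy(object), aes(.data$auc)) +
    geom_histogram(bins = 20, fill = "grey30") +
    labs(x = "Held-out AUC", y = "Permutations") +
    theme_minimal()
}

#' @method tidy repr_ensemble
#' @export
tidy.repr_ensemble <- function(x, ...) {
  tibble(member = names(x$members),
         class = c("penalized-spline additive model",
                   "probability random forest",
                   "gradient-boosted trees"),
         covariates = paste(x$covariates, collapse = ", "))
}

#' @method glance repr_ensemble
#' @export
glance.repr_ensemble <- function(x, ...) {
  tibble(n_members = length(x$members),
         n_covariates = length(x$covariates),
         n_presence = x$n_presence %||% NA_integer_,
         n_absence = x$n_absence %||% NA_integer_)
}
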