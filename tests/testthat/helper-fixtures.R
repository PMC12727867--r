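# Shared fixtures, all built in code.

# two articles: 12 citations over 4 locations, 7 citations over 2 locations
tiny_lit <- function() {
  lit_table(tibble::tibble(
    article_id = c(rep("a1", 4), rep("a2", 2)),
    total_citations = c(rep(12, 4), rep(7, 2)),
    longitude = c(-5, -4, -3, -2, 10, 11),
    latitude = c(0, 1, 2, 3, -5, -6),
    habitats = list("forest", "grassland", c("forest", "lake"), "wetland",
                    "desert", "river")
  ))
}

# deterministic small stack: two layers with simple arithmetic patterns
tiny_stack <- function(nr = 10, nc = 12, cellsize = 1,
                       xmin = 0, ymax = 5) {
  a <- matrix(seq_len(nr * nc), nr, nc)
  b <- matrix(rep(seq_len(nc), each = nr) * 10, nr, nc)
  env_stack(list(
    alpha = env_grid(a * 1.0, xmin, ymax, cellsize, "alpha"),
    beta = env_grid(b * 1.0, xmin, ymax, cellsize, "beta")
  ))
}

# rectangular ring (open; counterclockwise)
square_ring <- function(x0, x1, y0, y1) {
  rbind(c(x0, y0), c(x1, y0), c(x1, y1), c(x0, y1))
}

# small synthetic configuration used across tests (fast: 60 x 40 cells);
# overrides win over the fixture defaults
small_syncfg <- function(...) {
  defaults <- list(lon_range = c(-20, 20), lat_range = c(-30, 30),
                   cellsize = 1, n_articles = 120, seed = 11)
  do.call(synthetic_config, utils::modifyList(defaults, list(...)))
}

# cheap ensemble settings for unit tests
fast_model <- function() ensemble_config(rf_trees = 100, gbt_rounds = 100)

# exhaustive pairwise-concordance AUC oracle (O(n^2))
auc_pair_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  s <- 0
  for (p in pos) for (q in neg) {
    s <- s + (p > q) + 0.5 * (p == q)
  }
  s / (length(pos) * length(neg))
}
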