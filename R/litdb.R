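#' Canonical habitat vocabulary
#'
#' The nine habitat classes a sampling location may carry (at most three per
#' location). Labels are matched case-insensitively and common synonyms such
#' as "rocky area" are folded to the canonical form.
#'
#' @return Character vector of canonical habitat labels.
#' @export
habitat_vocabulary <- function() {
  c("forest", "grassland", "wetland", "desert", "rocky",
    "agricultural", "urban", "lake", "river")
}

habitat_synonyms <- c(
  "rocky area" = "rocky",
  "rocky areas" = "rocky",
  "agriculture" = "agricultural",
  "grasslands" = "grassland",
  "forests" = "forest",
  "wetlands" = "wetland",
  "deserts" = "desert",
  "lakes" = "lake",
  "rivers" = "river"
)

normalize_habitat <- function(x) {
  x <- tolower(trimws(x))
  hit <- x %in% names(habitat_synonyms)
  x[hit] <- unname(habitat_synonyms[x[hit]])
  x
}

#' Literature table: one row per (article, sampling location)
#'
#' `lit_table()` validates a data frame of geocoded sampling locations and
#' returns it as a `lit_table` tibble. Required columns: `article_id`,
#' `total_citations` (article-level, repeated on each of its rows),
#' `longitude`, `latitude`, and `habitats` (a list-column of 1-3 canonical
#' labels). An `allocated_citations` column is added by
#' [allocate_citations()].
#'
#' @param x A data frame with the columns above.
#' @return A validated `lit_table` tibble, rows in input order.
#' @export
lit_table <- function(x) {
  need <- c("article_id", "total_citations", "longitude", "latitude", "habitats")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols) > 0) {
    stop_tropirep(paste("missing required column(s):",
                        paste(missing_cols, collapse = ", ")), "schema_error")
  }
  x <- as_tibble(x)
  bad_coord <- which(!is.finite(x$longitude) | !is.finite(x$latitude) |
                       x$longitude < -180 | x$longitude > 180 |
                       x$latitude < -90 | x$latitude > 90)
  if (length(bad_coord) > 0) {
    stop_tropirep(paste("unparseable or out-of-range coordinates in row(s):",
                        paste(head(bad_coord, 10), collapse = ", ")),
                  "row_error")
  }
  bad_cit <- which(!is.finite(x$total_citations) | x$total_citations < 0)
  if (length(bad_cit) > 0) {
    stop_tropirep(paste("unparseable or negative citations in row(s):",
                        paste(head(bad_cit, 10), collapse = ", ")), "row_error")
  }
  x$habitats <- map(x$habitats, normalize_habitat)
  nh <- lengths(x$habitats)
  if (any(nh < 1)) {
    stop_tropirep(paste("empty habitat set in row(s):",
                        paste(head(which(nh < 1), 10), collapse = ", ")),
                  "validation_error")
  }
  if (any(nh > 3)) {
    stop_tropirep(paste("more than 3 habitats in row(s):",
                        paste(head(which(nh > 3), 10), collapse = ", ")),
                  "validation_error")
  }
  unknown <- setdiff(unique(unlist(x$habitats)), habitat_vocabulary())
  if (length(unknown) > 0) {
    stop_tropirep(paste("unknown habitat label(s):",
                        paste(unknown, collapse = ", ")), "validation_error")
  }
  per_article <- x |>
    group_by(.data$article_id) |>
    summarise(n = dplyr::n_distinct(.data$total_citations), .groups = "drop")
  if (any(per_article$n > 1)) {
    stop_tropirep("total_citations differs across rows of one article",
                  "validation_error")
  }
  class(x) <- c("lit_table", class(x))
  x
}

#' Read a geocoded literature database from CSV
#'
#' One row per (article, sampling location). The default schema expects
#' columns `article_id`, `citations`, `longitude`, `latitude`, `habitat1`
#' (and optionally `habitat2`, `habitat3`); `schema` remaps any of these to
#' other column names. Habitat labels are normalized to the canonical
#' lower-case vocabulary; a row listing more than three habitats, an unknown
#' label, or an out-of-range coordinate is an error naming the offending
#' rows or label.
#'
#' @param path CSV file path (UTF-8, '.' decimal point).
#' @param schema Named character vector mapping canonical names
#'   (`article_id`, `citations`, `longitude`, `latitude`, `habitat1`,
#'   `habitat2`, `habitat3`) to the file's column names.
#' @return A validated [lit_table()] with rows in file order.
#' @export
read_literature_table <- function(path, schema = NULL) {
  if (!file.exists(path)) stop_tropirep(paste("no such file:", path), "io_error")
  defaults <- c(article_id = "article_id", citations = "citations",
                longitude = "longitude", latitude = "latitude",
                habitat1 = "habitat1", habitat2 = "habitat2",
                habitat3 = "habitat3")
  if (!is.null(schema)) defaults[names(schema)] <- schema
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  required <- defaults[c("article_id", "citations", "longitude", "latitude",
                         "habitat1")]
  missing_cols <- setdiff(unname(required), names(raw))
  if (length(missing_cols) > 0) {
    stop_tropirep(paste("missing required column(s):",
                        paste(missing_cols, collapse = ", ")), "schema_error")
  }
  hab_cols <- intersect(unname(defaults[c("habitat1", "habitat2", "habitat3")]),
                        names(raw))
  habitats <- pmap(raw[hab_cols], function(...) {
    h <- as.character(c(...))
    # a single cell may also hold a ';'-separated list
    h <- unlist(strsplit(h[!is.na(h) & trimws(h) != ""], ";"))
    normalize_habitat(h)
  })
  lit_table(tibble(
    article_id = as.character(raw[[required["article_id"]]]),
    total_citations = suppressWarnings(as.numeric(raw[[required["citations"]]])),
    longitude = suppressWarnings(as.numeric(raw[[required["longitude"]]])),
    latitude = suppressWarnings(as.numeric(raw[[required["latitude"]]])),
    habitats = habitats
  ))
}

#' Article-level records of a literature table
#'
#' @param table A [lit_table()].
#' @return Tibble with `article_id`, `total_citations`, `n_locations`.
#' @export
article_records <- function(table) {
  table |>
    group_by(.data$article_id) |>
    summarise(total_citations = .data$total_citations[1],
              n_locations = dplyr::n(), .groups = "drop")
}

#' Allocate article citations equally across sampling locations
#'
#' Each location receives `total_citations / n_locations` for its article, so
#' per-article citation totals are conserved across locations.
#'
#' @param table A [lit_table()].
#' @return The table with an `allocated_citations` column.
#' @export
allocate_citations <- function(table) {
  out <- table |>
    group_by(.data$article_id) |>
    mutate(allocated_citations = .data$total_citations[1] / dplyr::n()) |>
    ungroup()
  class(out) <- class(table)
  out
}

#' Exclude locations in heavily human-modified habitats
#'
#' Removes every location whose habitat set intersects `excluded` (by default
#' urban and agricultural); articles left with no locations disappear from
#' the table. Citations are then re-allocated over the remaining locations
#' (`reallocate = TRUE`, the default) so each retained article's full
#' citation weight stays in the table, or kept at their original per-location
#' values (`reallocate = FALSE`).
#'
#' @param table A [lit_table()].
#' @param excluded Habitat labels to exclude.
#' @param reallocate Recompute allocated citations over remaining locations.
#' @return Filtered `lit_table`, with a `filter_report` attribute holding
#'   before/after counts (see [filter_report()]).
#' @export
filter_natural_habitats <- function(table,
                                    excluded = c("urban", "agricultural"),
                                    reallocate = TRUE) {
  excluded <- normalize_habitat(excluded)
  unknown <- setdiff(excluded, habitat_vocabulary())
  if (length(unknown) > 0) {
    stop_tropirep(paste("unknown habitat label(s) in `excluded`:",
                        paste(unknown, collapse = ", ")), "validation_error")
  }
  before <- summarize_counts(table)
  keep <- map_lgl(table$habitats, function(h) !any(h %in% excluded))
  out <- table[keep, , drop = FALSE]
  if (reallocate || !("allocated_citations" %in% names(out))) {
    out <- allocate_citations(out)
  }
  class(out) <- class(table)
  attr(out, "filter_report") <- list(
    excluded = excluded,
    before = before,
    after = summarize_counts(out)
  )
  out
}

#' @rdname filter_natural_habitats
#' @export
filter_report <- function(table) attr(table, "filter_report")

#' Headline counts of a literature table
#'
#' @param table A [lit_table()].
#' @return One-row tibble: `n_articles`, `n_locations`, `total_citations`
#'   (sum of article-level totals over retained articles).
#' @export
summarize_counts <- function(table) {
  if (nrow(table) == 0) {
    return(tibble(n_articles = 0L, n_locations = 0L, total_citations = 0))
  }
  arts <- article_records(table)
  tibble(
    n_articles = nrow(arts),
    n_locations = nrow(table),
    total_citations = sum(arts$total_citations)
  )
}

#' Write a JSON report of habitat filtering
#'
#' @param table A table returned by [filter_natural_habitats()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_filter_report <- function(table, path) {
  rep <- filter_report(table)
  if (is.null(rep)) stop_tropirep("table carries no filter report", "io_error")
  jsonlite::write_json(
    list(excluded = rep$excluded,
         before = as.list(rep$before), after = as.list(rep$after)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}
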