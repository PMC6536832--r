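#' The four FoodEx2 food categories
#' @return Character vector of the closed category set.
#' @export
food_categories <- function() {
  c("raw", "derivative", "simple composite", "aggregated composite")
}

#' Construct a food catalogue
#'
#' A FoodEx2-like catalogue: one row per food with a unique list-term code, a
#' name and one of the four food categories. Each entry's name is profiled
#' (see [text_profile()]) at load time and a noun index (noun lemma to entry
#' ids) is built for candidate retrieval.
#'
#' @param df Data frame with columns `code`, `name`, `category`.
#' @return A list of class `food_catalogue` with elements `entries` (tibble),
#'   `profiles` (list of [text_profile()]s) and `noun_index` (named list:
#'   noun lemma -> integer entry ids).
#' @export
food_catalogue <- function(df) {
  df <- tibble::as_tibble(df)[, c("code", "name", "category")]
  if (anyDuplicated(df$code)) {
    stop("duplicate catalogue code: ", df$code[duplicated(df$code)][1])
  }
  if (any(!nzchar(df$name))) stop("catalogue names must be non-empty")
  bad <- setdiff(unique(df$category), food_categories())
  if (length(bad)) stop("unknown food category: '", bad[1], "'")
  profiles <- lapply(df$name, text_profile)
  noun_index <- list()
  for (i in seq_along(profiles)) {
    for (noun in profiles[[i]]$nouns) {
      noun_index[[noun]] <- c(noun_index[[noun]], i)
    }
  }
  structure(
    list(entries = df, profiles = profiles, noun_index = noun_index),
    class = "food_catalogue"
  )
}

#' Number of catalogue entries
#' @param x A `food_catalogue`.
#' @param ... Unused.
#' @export
length.food_catalogue <- function(x) nrow(x$entries)

#' @export
print.food_catalogue <- function(x, ...) {
  cat("<food_catalogue> ", nrow(x$entries), " entries, ",
    length(x$noun_index), " indexed noun lemmas\n",
    sep = ""
  )
  invisible(x)
}

#' Read a catalogue CSV (`code,name,category`)
#' @param path CSV path.
#' @return A [food_catalogue()].
#' @export
read_catalogue <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("code", "name", "category") %in% names(df))) {
    stop("catalogue CSV must have header code,name,category")
  }
  food_catalogue(df)
}

#' Write a catalogue CSV
#' @param catalogue A [food_catalogue()].
#' @param path Output path.
#' @export
write_catalogue <- function(catalogue, path) {
  readr::write_csv(catalogue$entries, path)
  invisible(path)
}

#' Read a food composition table keyed by FoodEx2-style code
#'
#' Expected header: `code,name,energy_kcal,protein_g,carbohydrate_g,fat_g`
#' (additional nutrient columns pass through). Codes must be unique and
#' nutrient amounts non-negative; both are enforced at load time so lookup
#' is never ambiguous.
#'
#' @param path CSV path.
#' @return Tibble of class `fcdb`.
#' @export
read_fcdb <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  fcdb(df)
}

#' @rdname read_fcdb
#' @param df Data frame with a `code` column and numeric nutrient columns.
#' @export
fcdb <- function(df) {
  df <- tibble::as_tibble(df)
  if (!"code" %in% names(df)) stop("FCDB must have a 'code' column")
  if (anyDuplicated(df$code)) {
    stop("duplicate FCDB code: ", df$code[duplicated(df$code)][1])
  }
  nutrient_cols <- setdiff(names(df), c("code", "name"))
  for (col in nutrient_cols) {
    if (any(df[[col]] < 0, na.rm = TRUE)) {
      stop("negative nutrient amount in column ", col)
    }
  }
  class(df) <- c("fcdb", class(df))
  df
}

#' Write an FCDB CSV
#' @param x An [fcdb()] tibble.
#' @param path Output path.
#' @export
write_fcdb <- function(x, path) {
  readr::write_csv(tibble::as_tibble(unclass(x)), path)
  invisible(path)
}

#' Look up the nutrient record for a standardized food
#'
#' Keyed solely by the resolved FoodEx2-style code. A missing code raises a
#' not-found error carrying the code, so callers may fall back to
#' standardizing the FCDB's own names to recover identifiers.
#'
#' @param food A [standardize_food()] result, or a code string.
#' @param fcdb_tbl An [fcdb()] table.
#' @return The matching one-row nutrient record (tibble).
#' @export
link_fcdb <- function(food, fcdb_tbl) {
  code <- if (inherits(food, "standardized_food")) food$code else as.character(food)
  if (is.null(code) || is.na(code) || !nzchar(code)) {
    stop("food has no resolved code")
  }
  hit <- fcdb_tbl[fcdb_tbl$code == code, ]
  if (nrow(hit) == 0) {
    stop("FCDB code not found: ", code)
  }
  tibble::as_tibble(unclass(hit))
}
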