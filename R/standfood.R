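#' Profile a food name for matching
#'
#' Pre-processes a food name the way the standardization chain expects:
#' lowercase it, tokenize, tag each token with a part of speech and collect
#' the lemmatized noun, adjective and verb sets. Function words
#' ("with", "and", "of", ...) are dropped before tagging since they carry no
#' food meaning. Note that names such as "French dressing" or "herring"
#' legitimately yield an empty noun set under the gerund rule — that is the
#' case the Levenshtein fallback exists for.
#'
#' @param name Non-empty food name.
#' @param lexicons See [standfood_lexicons()].
#' @return A list of class `text_profile` with fields `original`,
#'   `normalized`, `nouns`, `adjectives`, `verbs` (lowercase lemma sets).
#' @export
text_profile <- function(name, lexicons = standfood_lexicons()) {
  if (length(name) != 1L || is.na(name) || !nzchar(trimws(name))) {
    stop("food name must be non-empty")
  }
  stop_words <- c(lexicons$connectors, "of", "in", "on", "a", "an", "the")
  tokens <- setdiff(tokenize(name), stop_words)
  tags <- pos_tag(tokens, lexicons)
  lemmas <- lemmatize(tokens)
  structure(
    list(
      original = name,
      normalized = tolower(name),
      nouns = unique(lemmas[tags == "noun"]),
      adjectives = unique(lemmas[tags == "adjective"]),
      verbs = unique(lemmas[tags == "verb"])
    ),
    class = "text_profile"
  )
}

#' Retrieve catalogue candidates sharing a noun with the query
#'
#' Returns exactly the entries whose name contains at least one of the
#' query's noun lemmas, via the catalogue's noun index. A query with no
#' nouns retrieves nothing — the caller then switches to the edit-distance
#' fallback.
#'
#' @param query A [text_profile()].
#' @param catalogue A [food_catalogue()].
#' @return Sorted integer vector of entry ids (possibly empty).
#' @export
retrieve_candidates <- function(query, catalogue) {
  stopifnot(inherits(query, "text_profile"), inherits(catalogue, "food_catalogue"))
  if (!length(query$nouns)) return(integer())
  ids <- unlist(catalogue$noun_index[query$nouns], use.names = FALSE)
  sort(unique(ids))
}

#' Score a query/candidate profile pair
#'
#' Part-of-speech-weighted Jaccard similarity over the lemma sets:
#' `(3 |noun int| + 2 |adj int| + 1 |verb int|) /
#'  (3 |noun uni| + 2 |adj uni| + 1 |verb uni|)`.
#' Nouns dominate, mirroring noun-driven retrieval; the weight is symmetric,
#' lies in `[0, 1]`, and equals 1 exactly when all three lemma sets coincide
#' (with a non-empty union). An empty union scores 0.
#'
#' @param query,candidate [text_profile()]s.
#' @param coefficients Named weights for the three parts of speech.
#' @return Weight in `[0, 1]`.
#' @export
score_pair <- function(query, candidate,
                       coefficients = c(noun = 3, adjective = 2, verb = 1)) {
  num <- coefficients[["noun"]] * length(intersect(query$nouns, candidate$nouns)) +
    coefficients[["adjective"]] * length(intersect(query$adjectives, candidate$adjectives)) +
    coefficients[["verb"]] * length(intersect(query$verbs, candidate$verbs))
  den <- coefficients[["noun"]] * length(union(query$nouns, candidate$nouns)) +
    coefficients[["adjective"]] * length(union(query$adjectives, candidate$adjectives)) +
    coefficients[["verb"]] * length(union(query$verbs, candidate$verbs))
  if (den == 0) return(0)
  num / den
}

#' Levenshtein edit distance between two food names
#'
#' Minimal number of single-character insertions, deletions and
#' substitutions (unit costs), computed case-insensitively on the whole
#' normalized names.
#'
#' @param a,b Strings.
#' @return Non-negative integer distance.
#' @export
food_levenshtein <- function(a, b) {
  as.integer(utils::adist(tolower(a), tolower(b))[1, 1])
}

#' Describe a food name against the catalogue
#'
#' The description step of the standardization chain. If noun-based
#' retrieval yields candidates, they are scored with [score_pair()] and
#' ranked by descending weight (ties broken by smaller edit distance between
#' normalized names, then by code); the best pair is returned together with
#' its catalogue food category. If the query has no nouns, or no catalogue
#' name shares one, the chain switches to the Levenshtein fallback: every
#' entry is ranked by ascending edit distance to the query and the nearest
#' name wins.
#'
#' @param name Food name to describe.
#' @param catalogue A [food_catalogue()].
#' @param top_k Number of ranked alternates to keep (default 5).
#' @param lexicons See [standfood_lexicons()].
#' @param coefficients Passed to [score_pair()].
#' @return A list of class `description_result`: `best` (one-row tibble),
#'   `alternates` (ranked tibble incl. the best), `method`
#'   (`"noun-index"` or `"levenshtein"`) and `match_category`.
#' @export
describe_food <- function(name, catalogue, top_k = 5,
                          lexicons = standfood_lexicons(),
                          coefficients = c(noun = 3, adjective = 2, verb = 1)) {
  stopifnot(inherits(catalogue, "food_catalogue"))
  if (length(catalogue) == 0) stop("catalogue is empty")
  query <- text_profile(name, lexicons)
  ids <- retrieve_candidates(query, catalogue)

  if (length(ids)) {
    method <- "noun-index"
    weight <- vapply(
      ids,
      function(i) score_pair(query, catalogue$profiles[[i]], coefficients),
      numeric(1)
    )
    distance <- vapply(
      ids,
      function(i) food_levenshtein(query$normalized, catalogue$profiles[[i]]$normalized),
      integer(1)
    )
    ranked <- tibble::tibble(
      id = ids,
      code = catalogue$entries$code[ids],
      name = catalogue$entries$name[ids],
      category = catalogue$entries$category[ids],
      weight = weight,
      distance = distance
    )
    ranked <- ranked[order(-ranked$weight, ranked$distance, ranked$code), ]
  } else {
    method <- "levenshtein"
    distance <- vapply(
      seq_len(length(catalogue)),
      function(i) food_levenshtein(query$normalized, catalogue$profiles[[i]]$normalized),
      integer(1)
    )
    ranked <- tibble::tibble(
      id = seq_len(length(catalogue)),
      code = catalogue$entries$code,
      name = catalogue$entries$name,
      category = catalogue$entries$category,
      weight = NA_real_,
      distance = distance
    )
    ranked <- ranked[order(ranked$distance, ranked$code), ]
  }

  structure(
    list(
      query = query,
      best = ranked[1, ],
      alternates = utils::head(ranked, top_k),
      method = method,
      match_category = ranked$category[1]
    ),
    class = "description_result"
  )
}

#' Classify a food name into one of the four food categories
#'
#' Transparent lexicon rule set standing in for a learned classifier:
#' 1. A name with at least two food nouns joined by a connector
#'    ("with", "and", a comma) or containing a recipe term ("salad", "soup",
#'    "sandwich", "pizza", ...) is a composite — aggregated when it has
#'    three or more food nouns or a recipe term, simple otherwise.
#' 2. Otherwise a name containing a process term ("dried", "smoked",
#'    "juice", "sauce", ...) is a derivative.
#' 3. Otherwise it is a raw food.
#' The lexicons are editable (see [standfood_lexicons()]); deterministic
#' given the configured lists.
#'
#' @param name Non-empty food name.
#' @param lexicons See [standfood_lexicons()].
#' @return One of `r paste(food_categories(), collapse = ", ")`.
#' @export
classify_food <- function(name, lexicons = standfood_lexicons()) {
  prof <- text_profile(name, lexicons)
  raw_tokens <- tokenize(name)
  lemmas <- lemmatize(raw_tokens)
  n_nouns <- length(prof$nouns)
  has_connector <- any(raw_tokens %in% lexicons$connectors) || grepl(",", name)
  recipe_hit <- any(lemmas %in% lexicons$recipe_terms)
  process_hit <- any(lemmas %in% lexicons$process_terms)
  if ((n_nouns >= 2 && has_connector) || recipe_hit) {
    if (n_nouns >= 3 || recipe_hit) {
      return("aggregated composite")
    }
    return("simple composite")
  }
  if (process_hit) {
    return("derivative")
  }
  "raw"
}

#' Combine classifier and description categories (post-processing)
#'
#' If the matched catalogue entry's category disagrees with the classifier's
#' and the match is strong — weight at least `weight_threshold` for
#' noun-index matches, or edit distance at most `distance_threshold` for
#' fallback matches — the match's category overrides the classifier and the
#' result is flagged as post-processed. Otherwise the classifier's category
#' stands.
#'
#' @param classifier_category Category from [classify_food()].
#' @param description A [describe_food()] result.
#' @param weight_threshold Minimum match weight to override (default 0.5).
#' @param distance_threshold Maximum fallback edit distance to override
#'   (default 2).
#' @return List with `category` and logical `post_processed`.
#' @export
post_process <- function(classifier_category, description,
                         weight_threshold = 0.5, distance_threshold = 2) {
  stopifnot(inherits(description, "description_result"))
  match_category <- description$match_category
  strong <- if (description$method == "levenshtein") {
    description$best$distance <= distance_threshold
  } else {
    description$best$weight >= weight_threshold
  }
  if (!identical(match_category, classifier_category) && isTRUE(strong)) {
    list(category = match_category, post_processed = TRUE)
  } else {
    list(category = classifier_category, post_processed = FALSE)
  }
}

#' Standardize a food name to a FoodEx2-style code and category
#'
#' Runs the full chain: profile and classify the name, describe it against
#' the catalogue (noun retrieval with weighted scoring, or the Levenshtein
#' fallback), then post-process the two category opinions. A name that is
#' verbatim a catalogue entry always resolves to that entry.
#'
#' @inheritParams describe_food
#' @param weight_threshold,distance_threshold See [post_process()].
#' @return A list of class `standardized_food`: `query`, `code`,
#'   `matched_name`, `final_category`, `classifier_category`,
#'   `match_category`, `method`, `post_processed`, `description`.
#' @export
standardize_food <- function(name, catalogue, top_k = 5,
                             lexicons = standfood_lexicons(),
                             coefficients = c(noun = 3, adjective = 2, verb = 1),
                             weight_threshold = 0.5, distance_threshold = 2) {
  description <- describe_food(name, catalogue, top_k, lexicons, coefficients)
  classifier_category <- classify_food(name, lexicons)
  pp <- post_process(classifier_category, description,
    weight_threshold, distance_threshold
  )
  structure(
    list(
      query = name,
      code = description$best$code,
      matched_name = description$best$name,
      final_category = pp$category,
      classifier_category = classifier_category,
      match_category = description$match_category,
      method = description$method,
      post_processed = pp$post_processed,
      description = description
    ),
    class = "standardized_food"
  )
}

#' @export
print.standardized_food <- function(x, ...) {
  cat(sprintf(
    "<standardized_food> '%s' -> %s ('%s'), category: %s [%s%s]\n",
    x$query, x$code, x$matched_name, x$final_category, x$method,
    if (x$post_processed) ", post-processed" else ""
  ))
  invisible(x)
}

#' Standardize a vector of food names
#'
#' @param names Character vector of food names.
#' @param catalogue A [food_catalogue()].
#' @param fcdb_tbl Optional [fcdb()] table; when given, each resolved code is
#'   linked and its linkage status reported.
#' @param ... Passed to [standardize_food()].
#' @return Tibble with one row per name: `query`, `code`, `matched_name`,
#'   `final_category`, `method`, `post_processed` and (with an FCDB)
#'   `linked`.
#' @export
standardize_names <- function(names, catalogue, fcdb_tbl = NULL, ...) {
  rows <- lapply(names, function(nm) {
    sf <- standardize_food(nm, catalogue, ...)
    out <- tibble::tibble(
      query = sf$query, code = sf$code, matched_name = sf$matched_name,
      final_category = sf$final_category, method = sf$method,
      post_processed = sf$post_processed
    )
    if (!is.null(fcdb_tbl)) {
      out$linked <- tryCatch(
        {
          link_fcdb(sf, fcdb_tbl)
          TRUE
        },
        error = function(e) FALSE
      )
    }
    out
  })
  dplyr::bind_rows(rows)
}
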