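#' Lexicons driving the rule-based tagger and the category classifier
#'
#' Editable word lists used by [pos_tag()] and [classify_food()]:
#' `adjectives` are descriptive modifiers commonly seen in food names;
#' `process_terms` signal a derivative (processed) food; `recipe_terms`
#' signal a composite dish; `connectors` join ingredient nouns in composite
#' names. Pass a modified copy to the relevant functions to retarget the
#' tagger to another catalogue's vocabulary.
#'
#' @return Named list of character vectors.
#' @export
standfood_lexicons <- function() {
  list(
    adjectives = c(
      "fresh", "dried", "french", "green", "red", "white", "black", "brown",
      "whole", "raw", "sweet", "sour", "hot", "cold", "mixed", "plain",
      "italian", "greek", "smoked", "fried", "baked", "boiled", "roasted",
      "grilled", "cooked", "canned", "frozen", "wholegrain", "skimmed"
    ),
    process_terms = c(
      "dried", "fried", "smoked", "cooked", "baked", "boiled", "roasted",
      "grilled", "canned", "dressing", "juice", "sauce", "bread", "cheese",
      "butter", "yoghurt", "jam", "oil"
    ),
    recipe_terms = c("salad", "soup", "sandwich", "pizza", "stew", "risotto"),
    connectors = c("with", "and")
  )
}

#' Tokenize a food name
#'
#' Lowercases and splits on any non-letter character, so commas and
#' connectors separate cleanly.
#'
#' @param text Food name.
#' @return Character vector of lowercase tokens.
#' @export
tokenize <- function(text) {
  toks <- unlist(strsplit(tolower(text), "[^a-z]+"))
  toks[nzchar(toks)]
}

#' Rule-based part-of-speech tagging of food-name tokens
#'
#' A deterministic surface-form tagger: a token in the adjective lexicon is
#' an adjective; a token ending in "-ing" is tagged as a verb (gerund) — this
#' is why names such as "dressing" or "herring" yield no nouns and the
#' description step must fall back to edit distance; a token ending in "-ed"
#' is a participial adjective; everything else is a noun. No external model
#' or download is involved, so tagging is fully reproducible.
#'
#' @param tokens Character vector from [tokenize()].
#' @param lexicons See [standfood_lexicons()].
#' @return Character vector of tags: `"noun"`, `"adjective"` or `"verb"`.
#' @export
pos_tag <- function(tokens, lexicons = standfood_lexicons()) {
  vapply(tokens, function(tok) {
    if (tok %in% lexicons$adjectives) return("adjective")
    if (endsWith(tok, "ing")) return("verb")
    if (endsWith(tok, "ed") && nchar(tok) > 3) return("adjective")
    "noun"
  }, character(1), USE.NAMES = FALSE)
}

#' Lemmatize a food-name token
#'
#' Suffix-stripping lemmatizer for English plurals: "-ies" to "-y",
#' sibilant "-es" dropped, trailing "-s" dropped (so "herrings" lemmatizes
#' to "herring"). Gerunds are kept whole.
#'
#' @param tokens Character vector of lowercase tokens.
#' @return Character vector of lemmas.
#' @export
lemmatize <- function(tokens) {
  vapply(tokens, function(tok) {
    n <- nchar(tok)
    if (endsWith(tok, "ies") && n > 4) {
      return(paste0(substr(tok, 1, n - 3), "y"))
    }
    for (suf in c("ses", "xes", "zes", "ches", "shes")) {
      if (endsWith(tok, suf)) return(substr(tok, 1, n - 2))
    }
    if (endsWith(tok, "s") && !endsWith(tok, "ss") && !endsWith(tok, "us") && n > 2) {
      return(substr(tok, 1, n - 1))
    }
    tok
  }, character(1), USE.NAMES = FALSE)
}
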