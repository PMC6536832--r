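test_that("profiling lowercases, tags and lemmatizes food names", {
  p <- text_profile("Tomato")
  expect_identical(p$normalized, "tomato")
  expect_true("tomato" %in% p$nouns)

  # gerund rule: no nouns for these names, as documented
  expect_length(text_profile("French dressing")$nouns, 0)
  expect_length(text_profile("herring")$nouns, 0)
  expect_identical(text_profile("French dressing")$adjectives, "french")

  fp <- text_profile("fresh pasta")
  expect_identical(fp$nouns, "pasta")
  expect_identical(fp$adjectives, "fresh")

  # plural lemmatization folds onto the singular
  expect_identical(lemmatize(c("tomatoes", "carrots", "berries")),
                   c("tomatoe", "carrot", "berry"))
  expect_identical(lemmatize("herrings"), "herring")

  expect_error(text_profile("   "), "non-empty")
  expect_error(text_profile(""), "non-empty")
})

test_that("candidate retrieval is exactly noun-lemma intersection", {
  ctl <- toy_catalogue()
  hits <- retrieve_candidates(text_profile("pasta"), ctl)
  expect_true(all(c("fresh pasta", "dried pasta") %in% ctl$entries$name[hits]))
  expect_length(retrieve_candidates(text_profile("herring"), ctl), 0)
  expect_length(retrieve_candidates(text_profile("quinoa"), ctl), 0)
})

test_that("pair weights are a bounded symmetric POS-weighted Jaccard", {
  ctl <- toy_catalogue()
  q <- text_profile("pasta")
  fresh <- text_profile("fresh pasta")
  expect_equal(score_pair(q, q), 1.0)
  expect_equal(score_pair(fresh, fresh), 1.0)
  w <- score_pair(q, fresh)
  expect_equal(w, 3 / 5) # 3*1 noun over 3*1 noun + 2*1 adjective
  expect_gt(w, 0)
  expect_lt(w, 1)
  expect_equal(score_pair(text_profile("pear"), text_profile("banana")), 0)
  # symmetry over random profile pairs from the catalogue
  withr::with_seed(51, {
    for (trial in 1:10) {
      ij <- sample(length(ctl), 2)
      expect_equal(
        score_pair(ctl$profiles[[ij[1]]], ctl$profiles[[ij[2]]]),
        score_pair(ctl$profiles[[ij[2]]], ctl$profiles[[ij[1]]])
      )
    }
  })
})

test_that("edit distance matches the recursive oracle and the metric axioms", {
  expect_identical(food_levenshtein("herring", "herrings"), 1L)
  expect_identical(food_levenshtein("kitten", "sitting"), 3L)
  expect_identical(food_levenshtein("", "pear"), 4L)
  expect_identical(food_levenshtein("pear", "pear"), 0L)
  withr::with_seed(52, {
    for (trial in 1:40) {
      a <- random_string(6)
      b <- random_string(6)
      c <- random_string(6)
      d <- food_levenshtein(a, b)
      expect_identical(d, as.integer(oracle_lev(a, b)))
      expect_identical(d, food_levenshtein(b, a)) # symmetry
      expect_identical(food_levenshtein(a, a), 0L) # identity
      expect_lte(d, food_levenshtein(a, c) + food_levenshtein(c, b)) # triangle
    }
  })
})

test_that("description falls back to edit distance only without noun candidates", {
  ctl <- toy_catalogue()
  h <- describe_food("herring", ctl)
  expect_identical(h$method, "levenshtein")
  expect_identical(h$best$name, "herrings")

  fd <- describe_food("French dressing", ctl)
  expect_identical(fd$method, "levenshtein")
  expect_identical(fd$best$name, "salad dressing")

  p <- describe_food("pasta", ctl)
  expect_identical(p$method, "noun-index")
  expect_setequal(p$alternates$name[1:2], c("fresh pasta", "dried pasta"))

  # whenever retrieval yields a candidate the method is never levenshtein
  for (nm in ctl$entries$name) {
    if (length(retrieve_candidates(text_profile(nm), ctl))) {
      expect_identical(describe_food(nm, ctl)$method, "noun-index")
    }
  }
  # ranking weights are non-increasing
  expect_true(all(diff(p$alternates$weight) <= 0))
  expect_error(describe_food("pear", food_catalogue(
    data.frame(code = character(), name = character(), category = character())
  )), "empty")
})

test_that("the category classifier follows the lexicon rules", {
  expect_identical(classify_food("tomato"), "raw")
  expect_identical(classify_food("pear"), "raw")
  expect_identical(classify_food("dried pasta"), "derivative")
  expect_identical(classify_food("apple juice"), "derivative")
  expect_identical(classify_food("French dressing"), "derivative")
  expect_identical(classify_food("rice with peas"), "simple composite")
  expect_identical(classify_food("bread with butter"), "simple composite")
  expect_identical(classify_food("pasta salad with tuna and egg"), "aggregated composite")
  expect_identical(classify_food("vegetable soup"), "aggregated composite")
  expect_error(classify_food("  "), "non-empty")
})

test_that("post-processing overrides the classifier only on strong matches", {
  # agreement: flag stays clear
  ctl <- toy_catalogue()
  agree <- describe_food("tomato", ctl)
  pp <- post_process("raw", agree)
  expect_identical(pp$category, "raw")
  expect_false(pp$post_processed)

  # strong disagreement (weight 1.0 >= 0.5): match category wins, flag set
  mislabelled <- food_catalogue(data.frame(
    code = "Z1", name = "tomato", category = "derivative"
  ))
  strong <- describe_food("tomato", mislabelled)
  pp2 <- post_process("raw", strong)
  expect_identical(pp2$category, "derivative")
  expect_true(pp2$post_processed)

  # weak disagreement (weight below threshold): classifier kept, flag clear
  weak_ctl <- food_catalogue(data.frame(
    code = "Z2", name = "tomato soup with rice and beans", category = "aggregated composite"
  ))
  weak <- describe_food("tomato", weak_ctl)
  expect_lt(weak$best$weight, 0.5)
  pp3 <- post_process("raw", weak)
  expect_identical(pp3$category, "raw")
  expect_false(pp3$post_processed)

  # fallback route: distance 1 <= 2 allows an override
  fb_ctl <- food_catalogue(data.frame(
    code = "Z3", name = "herrings", category = "derivative"
  ))
  fb <- describe_food("herring", fb_ctl)
  pp4 <- post_process("raw", fb)
  expect_identical(pp4$category, "derivative")
  expect_true(pp4$post_processed)
})

test_that("standardize composes the chain with exact-match dominance", {
  ctl <- toy_catalogue()
  tbl <- toy_fcdb(ctl)
  for (i in seq_len(length(ctl))) {
    nm <- ctl$entries$name[i]
    sf <- standardize_food(nm, ctl)
    expect_identical(sf$code, ctl$entries$code[i])
    if (sf$method == "noun-index") expect_equal(sf$description$best$weight, 1.0)
  }
  h <- standardize_food("herring", ctl)
  expect_identical(h$matched_name, "herrings")
  expect_identical(h$final_category, "raw")
  p <- standardize_food("pasta", ctl)
  expect_gte(nrow(p$description$alternates), 2L) # alternates kept for the user
  res <- standardize_names(c("herring", "pasta", "tomato"), ctl, tbl)
  expect_true(all(res$linked))
})
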