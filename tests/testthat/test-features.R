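# tiny taxonomy where depth(cat)=10, depth(dog)=8 style values are known
feat_taxonomy <- function() fig_taxonomy()

test_that("type/token counts and mean SDI follow the documented reading", {
  tax <- feat_taxonomy()
  # cat twice + door once: 2 noun types, 3 open tokens, depths 10 and 7
  toks <- toy_tokens(c("cat", "cat", "door"))
  p <- extract_features(toks, tax)
  expect_equal(p$n_noun_types, 2L)
  expect_equal(p$n_open_tokens, 3L)
  expect_equal(p$mean_occurrences, 1.5)
  expect_equal(p$mean_sdi, (10 + 7) / 2)
  expect_equal(p$sdi_coverage, 1)
  expect_equal(p$n_correct_sentences, 1L)
})

test_that("closed-class-only speech leaves lexical-depth fields undefined", {
  tax <- feat_taxonomy()
  toks <- toy_tokens(c("the", "and"), word_class = "closed")
  p <- extract_features(toks, tax)
  expect_true(is.na(p$mean_sdi))
  expect_equal(p$sdi_coverage, 0)
  expect_equal(p$n_closed_tokens, 2L)
  expect_equal(p$n_open_tokens, 0L)
  expect_true(is.na(p$mean_occurrences))
})

test_that("a single root-adjacent open token scores mean SDI 1", {
  p <- extract_features(toy_tokens("thing"), feat_taxonomy())
  expect_equal(p$mean_sdi, 1)
})

test_that("excluded tokens, tags, events and well-formedness are tallied", {
  tax <- feat_taxonomy()
  toks <- dplyr::bind_rows(
    toy_tokens(c("cat", "water"),
      utt_id = 1L, well_formed = TRUE,
      events = "anomic_pause,anomic_pause,cda",
      error_tags = c(".", "semantic_paraphasia")
    ),
    toy_tokens("uh", word_class = "filler", utt_id = 2L, well_formed = FALSE),
    toy_tokens("door",
      utt_id = 2L, well_formed = FALSE,
      error_tags = "phonemic_paraphasia"
    ),
    toy_tokens("sink", utt_id = 3L, well_formed = FALSE, error_tags = "false_start")
  )
  p <- extract_features(toks, tax)
  expect_equal(p$n_open_tokens, 3L)   # filler and false start excluded
  expect_equal(p$n_noun_types, 3L)
  expect_equal(p$n_phonemic_paraphasias, 1L)
  expect_equal(p$n_semantic_paraphasias, 1L)
  expect_equal(p$n_anomic_pauses, 2L)
  expect_equal(p$n_cda, 1L)
  expect_equal(p$n_correct_sentences, 1L)
})

test_that("type weighting ignores repetition; token weighting does not", {
  tax <- feat_taxonomy()
  toks <- toy_tokens(c("cat", "cat", "cat", "thing"))
  p_type <- extract_features(toks, tax, sdi_weighting = "type")
  p_tok <- extract_features(toks, tax, sdi_weighting = "token")
  expect_equal(p_type$mean_sdi, (10 + 1) / 2)
  expect_equal(p_tok$mean_sdi, (10 * 3 + 1) / 4)
  # repetition invariance under type weighting
  p_once <- extract_features(toy_tokens(c("cat", "thing")), tax)
  expect_equal(p_type$mean_sdi, p_once$mean_sdi)
})

test_that("per-speaker identity mean_occurrences * open types = open tokens", {
  co <- simulate_cohort(cohort_config(seed = 11, n_sv = 3, n_lv = 3))
  p <- co$profiles
  expect_equal(p$mean_occurrences * p$n_open_types, as.double(p$n_open_tokens))
})

test_that("words missing from taxonomy or lexicon are skipped, not imputed", {
  tax <- feat_taxonomy()
  lex <- tibble::tibble(lemma = c("cat", "door"), pos = NA_character_, fpm = c(10, 30))
  toks <- toy_tokens(c("cat", "door", "unicorn"))
  p <- extract_features(toks, tax, freq_lex = lex)
  expect_equal(p$sdi_coverage, 2 / 3)
  expect_equal(p$mean_sdi, (10 + 7) / 2)  # unicorn skipped
  expect_equal(p$mean_fu, 20)             # unicorn not zero-imputed
})

test_that("group summaries use the sample SD and reject absent groups", {
  prof <- tibble::tibble(
    speaker = c("a", "b"), group = "g1",
    mean_sdi = c(3, 5)
  )
  gs <- group_summary(prof, "g1")
  expect_equal(gs$mean[gs$feature == "mean_sdi"], 4)
  expect_equal(gs$sd[gs$feature == "mean_sdi"], sqrt(2))
  expect_error(group_summary(prof, "g2"), "not present")
})

test_that("profile_table enforces order and unique speakers", {
  co <- simulate_cohort(cohort_config(seed = 12, n_sv = 2, n_lv = 2))
  tab <- profile_table(co$profiles)
  expect_equal(
    names(tab),
    c("speaker", "group", semdepth:::feature_order)
  )
  expect_equal(nrow(tab), 4L)
  expect_error(
    profile_table(dplyr::bind_rows(co$profiles, co$profiles[1, ])),
    "duplicate speaker"
  )
  expect_error(extract_features(co$tokens[0, ], co$taxonomy), "empty")
})
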