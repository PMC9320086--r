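test_that("generated taxonomies have the advertised size and pass validation", {
  tax <- gen_taxonomy(seed = 1, branching = 2, max_depth = 3)
  expect_equal(nrow(tax$synsets), 15L)  # 2^4 - 1
  expect_equal(max(tax$synsets$depth), 3L)
  expect_length(tax$roots, 1L)
  tax3 <- gen_taxonomy(seed = 1, n_roots = 2, branching = 3, max_depth = 2)
  expect_equal(nrow(tax3$synsets), 2L * 13L)
  expect_length(tax3$roots, 2L)
  expect_error(gen_taxonomy(max_depth = 0), "max_depth")
})

test_that("equal seeds give byte-identical synthetic cohorts", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulate_cohort(cohort_config(seed = 77, n_sv = 3, n_lv = 4, n_hc = 3), out_dir = d1)
  simulate_cohort(cohort_config(seed = 77, n_sv = 3, n_lv = 4, n_hc = 3), out_dir = d2)
  for (f in c("taxonomy.tsv", "transcripts.tsv", "frequency-lexicon.tsv", "thickness.tsv", "config.txt")) {
    expect_identical(
      readBin(file.path(d1, f), "raw", file.size(file.path(d1, f))),
      readBin(file.path(d2, f), "raw", file.size(file.path(d2, f))),
      info = f
    )
  }
  # a different seed changes the data
  d3 <- withr::local_tempdir()
  simulate_cohort(cohort_config(seed = 78, n_sv = 3, n_lv = 4, n_hc = 3), out_dir = d3)
  expect_false(identical(
    readBin(file.path(d1, "transcripts.tsv"), "raw", file.size(file.path(d1, "transcripts.tsv"))),
    readBin(file.path(d3, "transcripts.tsv"), "raw", file.size(file.path(d3, "transcripts.tsv")))
  ))
})

test_that("generated files pass the package readers without warnings", {
  d <- withr::local_tempdir()
  co <- simulate_cohort(cohort_config(seed = 5, n_sv = 3, n_lv = 4, n_hc = 3), out_dir = d)
  expect_no_warning({
    tax <- read_taxonomy(file.path(d, "taxonomy.tsv"))
    toks <- read_transcripts(file.path(d, "transcripts.tsv"))
    lex <- read_frequency_lexicon(file.path(d, "frequency-lexicon.tsv"))
    tt <- read_thickness(file.path(d, "thickness.tsv"))
  })
  expect_equal(nrow(toks), nrow(co$tokens))
  expect_equal(sort(unique(tt$subject)), sort(c(co$profiles$speaker, sprintf("hc%02d", 1:3))))
})

test_that("stronger depth preference produces stochastically deeper speech", {
  tax <- gen_taxonomy(seed = 2)
  shallow <- cohort_config(
    seed = 31, n_sv = 12, n_lv = 0,
    theta = c(svPPA = -1.4, lvPPA = -0.8)
  )
  deep <- cohort_config(
    seed = 31, n_sv = 12, n_lv = 0,
    theta = c(svPPA = -0.4, lvPPA = -0.8)
  )
  m_shallow <- mean(feature_profiles(gen_transcripts(shallow, tax), tax)$mean_sdi)
  m_deep <- mean(feature_profiles(gen_transcripts(deep, tax), tax)$mean_sdi)
  expect_lt(m_shallow, m_deep)
  # monotone over a theta grid (empirical means at generous sample size)
  grid <- c(-1.6, -0.9, -0.2)
  means <- vapply(seq_along(grid), function(i) {
    cfg <- cohort_config(
      seed = 40 + i, n_sv = 15, n_lv = 0,
      theta = c(svPPA = grid[i], lvPPA = 0)
    )
    mean(feature_profiles(gen_transcripts(cfg, tax), tax)$mean_sdi)
  }, 0)
  expect_true(all(diff(means) > 0))
})

test_that("svPPA-like speakers score lower mean SDI than lvPPA-like ones", {
  # group-conditioned depth preference orders the group means
  tax <- merge_taxonomies(
    gen_taxonomy(seed = 1),
    gen_taxonomy(seed = 1, branching = 2, max_depth = 5, pos = "verb")
  )
  wins <- vapply(1:20, function(i) {
    cfg <- cohort_config(seed = 500 + i, n_sv = 12, n_lv = 12)
    p <- feature_profiles(gen_transcripts(cfg, tax), tax)
    mean(p$mean_sdi[p$group == "svPPA"]) < mean(p$mean_sdi[p$group == "lvPPA"])
  }, TRUE)
  expect_gte(mean(wins), 0.9)
})

test_that("theta = 0 recovers the uniform-over-lemmas depth distribution", {
  tax <- gen_taxonomy(seed = 3, branching = 2, max_depth = 5)
  cfg <- cohort_config(
    seed = 55, n_sv = 10, n_lv = 0,
    theta = c(svPPA = 0, lvPPA = 0), theta_sd = 0,
    open_tokens = c(svPPA = 600, lvPPA = 0), adj_prop = 0
  )
  toks <- gen_transcripts(cfg, tax)
  open <- toks[!toks$excluded & toks$word_class == "noun", ]
  depths <- semdepth:::open_lemma_pool(tax)
  obs <- table(factor(
    depths$depth[match(open$lemma, depths$lemma)],
    levels = 0:5
  ))
  expected_p <- as.vector(table(factor(depths$depth, levels = 0:5))) / nrow(depths)
  gof <- suppressWarnings(stats::chisq.test(as.vector(obs), p = expected_p))
  expect_gt(gof$p.value, 0.001)
})

test_that("planted association and noise limits behave as designed", {
  co <- simulate_cohort(cohort_config(seed = 61, n_sv = 6, n_lv = 15))
  # noise -> 0 with beta > 0: sample r -> 1 in a designated ROI
  cfg0 <- cohort_config(seed = 61, n_sv = 6, n_lv = 15)
  cfg0$assoc$r_target <- 1 - 1e-9
  tt <- gen_thickness(cfg0, co$profiles)
  ent <- tt[tt$region == "entorhinal" & tt$hemisphere == "left" & tt$group != "HC", ]
  r <- pearson_r(
    co$profiles$mean_sdi[match(ent$subject, co$profiles$speaker)],
    ent$thickness
  )$r
  expect_gt(r, 0.999)
  # HC baselines track the configured means (left entorhinal 3.20 +- 3 SE)
  hc <- co$thickness[co$thickness$group == "HC" &
    co$thickness$region == "entorhinal" & co$thickness$hemisphere == "left", ]
  se <- 0.42 / sqrt(30)
  expect_lt(abs(mean(hc$thickness) - 3.20), 3 * se)
})
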