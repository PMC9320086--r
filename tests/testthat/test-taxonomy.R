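test_that("worked-example hierarchy yields the published depths", {
  tax <- fig_taxonomy()
  expect_length(intersect(tax$roots, tax$synsets$id[tax$synsets$pos == "noun"]), 1L)
  expect_equal(sdi(tax, "cat", "noun")$sdi, 10L)
  expect_equal(sdi(tax, "animal", "noun")$sdi, 3L)
  expect_equal(sdi(tax, "thing", "noun")$sdi, 1L)
  expect_equal(sdi(tax, "close", "verb")$sdi, 1L)
  expect_equal(sdi(tax, "come out", "verb")$sdi, 3L)
})

test_that("a single synset with no edges is its own root at depth 0", {
  tax <- taxonomy(tibble::tibble(id = "n1", pos = "noun", lemmas = "entity"))
  expect_equal(tax$roots, "n1")
  expect_equal(synset_depth(tax, "n1"), 0L)
  expect_equal(sdi(tax, "entity", "noun")$sdi, 0L)
})

test_that("cycles and dangling edges are rejected with the offender named", {
  syn <- tibble::tibble(id = c("A", "B"), pos = "noun", lemmas = c("a", "b"))
  expect_error(
    taxonomy(syn, tibble::tibble(hyponym = c("A", "B"), hypernym = c("B", "A"))),
    "cycle through synset: A"
  )
  expect_error(
    taxonomy(syn, tibble::tibble(hyponym = "A", hypernym = "C")),
    "unknown synset: C"
  )
  expect_error(synset_depth(fig_taxonomy(), "nope"), "unknown synset")
})

test_that("reader reports parse errors with line numbers", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("S\tn1\tnoun\tentity", "X\tn2\tnoun"), f)
  expect_error(read_taxonomy(f), "line 2")
  writeLines(c("S\tn1\tnoun"), f)
  expect_error(read_taxonomy(f), "line 1")
})

test_that("DAG depth is the minimum over all hypernym paths", {
  tax <- dag_taxonomy()
  # oracle: exhaustive enumeration of every root-directed path
  expect_setequal(all_path_lengths(tax, "s"), c(3L, 5L))
  expect_equal(synset_depth(tax, "s"), 3L)
  expect_equal(sdi(tax, "leaf", "noun", policy = "min_depth")$sdi, 3)
})

test_that("depth equals unique path length on trees (enumeration oracle)", {
  tax <- merge_taxonomies(
    gen_taxonomy(seed = 3, branching = 3, max_depth = 3),
    gen_taxonomy(seed = 3, branching = 2, max_depth = 4, pos = "verb")
  )
  for (id in tax$synsets$id) {
    paths <- all_path_lengths(tax, id)
    expect_length(paths, 1L)
    expect_equal(synset_depth(tax, id), paths)
  }
  # parent-child consistency across the whole graph
  e <- tax$edges
  expect_true(all(synset_depth(tax, e$hyponym) == synset_depth(tax, e$hypernym) + 1L))
})

test_that("sense policies agree on monosemous lemmas and differ as documented", {
  syn <- tibble::tibble(
    id = c("r", "m", "d1", "d2"), pos = "noun",
    lemmas = list("root", "mid", c("poly", "deep1"), c("poly2", "poly"))
  )
  edges <- tibble::tibble(
    hyponym = c("m", "d1", "d2"), hypernym = c("r", "m", "d1")
  )
  tax <- taxonomy(syn, edges)
  # "poly" occurs at depths 2 (d1, first sense) and 3 (d2)
  expect_equal(sdi(tax, "poly", "noun", "first_sense")$sdi, 2)
  expect_equal(sdi(tax, "poly", "noun", "min_depth")$sdi, 2)
  expect_equal(sdi(tax, "poly", "noun", "max_depth")$sdi, 3)
  expect_equal(sdi(tax, "poly", "noun", "mean_depth")$sdi, 2.5)
  for (pol in c("first_sense", "min_depth", "max_depth", "mean_depth")) {
    expect_equal(sdi(tax, "mid", "noun", pol)$sdi, 1, info = pol)
  }
  # absence is a result, not an error
  res <- sdi(tax, "ghost", "noun")
  expect_false(res$found)
  expect_true(is.na(res$sdi))
  expect_false(sdi(tax, "poly", "verb")$found)
})

test_that("coverage report counts found and missing per word class", {
  tax <- fig_taxonomy()
  words <- tibble::tibble(
    lemma = c("cat", "animal", "water", "unicorn"),
    pos = "noun"
  )
  cov <- coverage_report(words, tax)
  expect_equal(cov$coverage, 0.75)
  expect_equal(cov$by_pos$n_missing, 1L)
  expect_equal(cov$missing$lemma, "unicorn")
  all_found <- coverage_report(words[1:3, ], tax)
  expect_equal(all_found$coverage, 1)
  empty <- coverage_report(words[0, ], tax)
  expect_true(is.na(empty$coverage))
  expect_equal(nrow(empty$by_pos), 0L)
})

test_that("write_taxonomy round-trips bit-exactly on the canonical dialect", {
  tax <- fig_taxonomy()
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_taxonomy(tax, f1)
  tax2 <- read_taxonomy(f1)
  write_taxonomy(tax2, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)), readBin(f2, "raw", file.size(f2)))
  expect_equal(tidy(tax2)[order(tidy(tax2)$id), ], tidy(tax)[order(tidy(tax)$id), ])
  expect_equal(sdi(tax2, "cat", "noun")$sdi, 10L)
})

test_that("WordNet-format adapter reads hypernym graph and sense order", {
  d <- withr::local_tempdir()
  write_mini_wndb(d)
  tax <- taxonomy_from_wordnet(d)
  expect_length(intersect(tax$roots, tax$synsets$id[tax$synsets$pos == "noun"]), 1L)
  expect_equal(sdi(tax, "animal", "noun")$sdi, 1L)  # root-adjacent
  # index order decides sense rank: first sense of "cat" is the deep synset
  expect_equal(sdi(tax, "cat", "noun", "first_sense")$sdi, 2L)
  expect_equal(sdi(tax, "cat", "noun", "min_depth")$sdi, 1L)
  expect_equal(sdi(tax, "true cat", "noun")$sdi, 2L)  # multiword lemma
  expect_error(
    taxonomy_from_wordnet(file.path(d, "missing")),
    "read_taxonomy"
  )
})
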