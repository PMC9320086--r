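# fixtures built in code; file-based ones land in tempdir()

fig_taxonomy <- function() {
  read_taxonomy(system.file("extdata", "cat-hypernyms.tsv", package = "semdepth"))
}

# small DAG: s has two hypernym paths to the root, of 3 and 5 edges
dag_taxonomy <- function() {
  syn <- tibble::tibble(
    id = c("r", "a1", "a2", "b1", "b2", "b3", "b4", "s"),
    pos = "noun",
    lemmas = c("root", "a1", "a2", "b1", "b2", "b3", "b4", "leaf")
  )
  edges <- tibble::tibble(
    hyponym  = c("a1", "a2", "s",  "b1", "b2", "b3", "b4", "s"),
    hypernym = c("r",  "a1", "a2", "r",  "b1", "b2", "b3", "b4")
  )
  taxonomy(syn, edges)
}

# exhaustive enumeration of all root-directed hypernym paths from a synset;
# independent oracle for min-path depth
all_path_lengths <- function(tax, id) {
  e <- tax$edges
  recurse <- function(node, len) {
    ups <- e$hypernym[e$hyponym == node]
    if (!length(ups)) return(len)
    unlist(lapply(ups, function(u) recurse(u, len + 1L)))
  }
  recurse(id, 0L)
}

# token-table builder: word_class/error tags default to plain nouns
toy_tokens <- function(lemmas, word_class = "noun", speaker = "s1",
                       group = "svPPA", task = "cookie_theft",
                       utt_id = 1L, well_formed = TRUE, events = ".",
                       error_tags = ".") {
  d <- tibble::tibble(
    speaker = speaker, group = group, task = task, utt_id = utt_id,
    well_formed = well_formed, events = events,
    surface = lemmas, lemma = lemmas, word_class = word_class,
    error_tags = error_tags
  )
  semdepth:::finalize_tokens(d)
}

# write a miniature WordNet-database-format pair (index.noun/data.noun):
# entity <- animal <- cat, with "cat" also lemma of a second shallow synset
write_mini_wndb <- function(dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  data_lines <- c(
    "  1 license header line",
    "00000001 03 n 01 entity 0 000 | that which exists",
    "00000002 03 n 01 animal 0 001 @ 00000001 n 0000 | a living creature",
    "00000003 03 n 02 cat 0 true_cat 0 001 @ 00000002 n 0000 | a feline",
    "00000004 03 n 01 cat 0 001 @ 00000001 n 0000 | slang: a person"
  )
  idx_lines <- c(
    "  1 license header line",
    "entity n 1 0 1 0 00000001",
    "animal n 1 1 @ 1 0 00000002",
    "cat n 2 1 @ 2 0 00000003 00000004",
    "true_cat n 1 1 @ 1 0 00000003"
  )
  writeLines(data_lines, file.path(dir, "data.noun"))
  writeLines(idx_lines, file.path(dir, "index.noun"))
  invisible(dir)
}

# brute-force Mann-Whitney oracle: pair counting and full enumeration
# of the permutation null for the exact two-sided p
brute_mwu <- function(x, y) {
  u1 <- sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  u2 <- length(x) * length(y) - u1
  list(u1 = u1, u2 = u2, u_reported = min(u1, u2))
}

brute_exact_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  idx <- utils::combn(length(pooled), n1)
  us <- apply(idx, 2, function(ii) {
    brute_mwu(pooled[ii], pooled[-ii])$u1
  })
  u_obs <- brute_mwu(x, y)$u1
  mu <- n1 * length(y) / 2
  # two-sided: double the smaller tail (as the implementation defines it)
  if (u_obs > mu) {
    min(1, 2 * mean(us >= u_obs))
  } else {
    min(1, 2 * mean(us <= u_obs))
  }
}

# classical BH step-up oracle: largest k with p_(k) <= k q / m rejected
bh_stepup_reject <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- which(ps <= seq_len(m) * q / m)
  rej <- rep(FALSE, m)
  if (length(k)) rej[o[seq_len(max(k))]] <- TRUE
  rej
}
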