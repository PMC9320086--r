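#' Read a word-frequency lexicon
#'
#' Two-column tab-separated `lemma<TAB>fpm` (frequency per million), with an
#' optional third `pos` column. When `pos` is present, frequency lookup is
#' per (lemma, pos); otherwise per lemma.
#'
#' @param path File path. `#` comment lines allowed.
#' @return Tibble with columns `lemma`, `fpm`, and `pos` (NA when absent).
#' @export
read_frequency_lexicon <- function(path) {
  if (!file.exists(path)) abort(paste0("frequency lexicon not found: ", path))
  d <- readr::read_tsv(
    path,
    comment = "#", show_col_types = FALSE, progress = FALSE
  )
  if (!all(c("lemma", "fpm") %in% names(d))) {
    abort("frequency lexicon needs columns `lemma` and `fpm`")
  }
  if (any(d$fpm < 0, na.rm = TRUE)) abort("negative frequency in lexicon")
  if (!"pos" %in% names(d)) d$pos <- NA_character_
  d %>%
    mutate(lemma = tolower(.data$lemma)) %>%
    select("lemma", "pos", "fpm")
}

#' Write a frequency lexicon
#' @param lex Tibble as returned by [read_frequency_lexicon()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_frequency_lexicon <- function(lex, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(
    c(
      "lemma\tpos\tfpm",
      paste(lex$lemma, lex$pos, format(lex$fpm, trim = TRUE, scientific = FALSE), sep = "\t")
    ),
    con, useBytes = TRUE
  )
  invisible(path)
}

# canonical feature column order (the order features are reported in)
feature_order <- c(
  "n_noun_types", "n_verb_types", "n_adj_types",
  "n_open_tokens", "n_closed_tokens", "n_correct_sentences",
  "n_phonemic_paraphasias", "n_semantic_paraphasias",
  "n_anomic_pauses", "n_cda",
  "mean_occurrences", "mean_sdi", "mean_fu"
)

#' Per-speaker microlinguistic feature profiles
#'
#' Reduces an annotated token table to one row per speaker:
#' \itemize{
#'   \item noun/verb/adjective counts are distinct-lemma (type) counts;
#'     open- and closed-class counts are token counts. Fillers and false
#'     starts (`excluded`) never enter lexical counts. Adverbs count toward
#'     open-class tokens/types but have no dedicated type counter.
#'   \item `mean_occurrences` = open tokens / open types, exactly.
#'   \item `mean_sdi` averages the Semantic Depth Index over scored
#'     open-class types (default) or tokens; words absent from the taxonomy
#'     are skipped, never imputed, and `sdi_coverage` records the scored
#'     fraction of open types.
#'   \item `mean_fu` averages corpus frequency over open types found in the
#'     lexicon (no zero-imputation).
#'   \item error counts sum token tags; anomic pauses and conduites
#'     d'approche are utterance-level events; `n_correct_sentences` counts
#'     well-formed utterances.
#' }
#'
#' @param tokens Token tibble from [read_transcripts()] (any number of
#'   speakers/tasks).
#' @param tax A [taxonomy()].
#' @param freq_lex Optional frequency lexicon from
#'   [read_frequency_lexicon()].
#' @param policy Sense policy passed to [sdi()].
#' @param sdi_weighting `"type"` (default) or `"token"` averaging for
#'   `mean_sdi`.
#' @return Tibble, one row per speaker: `speaker`, `group`, the thirteen
#'   features in canonical order, and `sdi_coverage`.
#' @export
feature_profiles <- function(tokens, tax, freq_lex = NULL,
                             policy = "first_sense",
                             sdi_weighting = c("type", "token")) {
  sdi_weighting <- match.arg(sdi_weighting)
  tokens <- as_tibble(tokens)
  if (nrow(tokens) == 0L) abort("empty transcript")

  lex_tok <- tokens %>% filter(!.data$excluded, .data$word_class != "filler")
  open_tok <- lex_tok %>% filter(.data$word_class %in% open_classes)

  # unique open-class types per speaker, scored once
  types <- open_tok %>%
    distinct(.data$speaker, .data$lemma, .data$word_class) %>%
    rename(pos = "word_class")
  types <- add_sdi(types, tax, policy = policy)
  if (!is.null(freq_lex)) {
    by_pos <- !all(is.na(freq_lex$pos))
    if (by_pos) {
      types <- types %>% left_join(freq_lex, by = c("lemma", "pos"))
    } else {
      types <- types %>% left_join(freq_lex[, c("lemma", "fpm")], by = "lemma")
    }
  } else {
    types$fpm <- NA_real_
  }

  type_stats <- types %>%
    group_by(.data$speaker) %>%
    summarise(
      n_noun_types = sum(.data$pos == "noun"),
      n_verb_types = sum(.data$pos == "verb"),
      n_adj_types = sum(.data$pos == "adjective"),
      n_open_types = n(),
      mean_sdi_type = if (any(.data$found)) mean(.data$sdi[.data$found]) else NA_real_,
      sdi_coverage = if (n() > 0) mean(.data$found) else 0,
      mean_fu = if (any(!is.na(.data$fpm))) mean(.data$fpm, na.rm = TRUE) else NA_real_,
      .groups = "drop"
    )

  token_sdi <- if (sdi_weighting == "token") {
    open_tok %>%
      select("speaker", "lemma", pos = "word_class") %>%
      left_join(
        types %>% select("speaker", "lemma", "pos", "sdi", "found"),
        by = c("speaker", "lemma", "pos")
      ) %>%
      group_by(.data$speaker) %>%
      summarise(
        mean_sdi_token = if (any(.data$found)) mean(.data$sdi[.data$found]) else NA_real_,
        .groups = "drop"
      )
  } else {
    NULL
  }

  tags <- split_tags(tokens$error_tags)
  tok_stats <- tokens %>%
    mutate(
      is_phon = vapply(tags, function(t) sum(t == "phonemic_paraphasia"), 0),
      is_sem = vapply(tags, function(t) sum(t == "semantic_paraphasia"), 0)
    ) %>%
    group_by(.data$speaker) %>%
    summarise(
      group = first(.data$group),
      n_open_tokens = sum(!.data$excluded & .data$word_class %in% open_classes),
      n_closed_tokens = sum(!.data$excluded & .data$word_class == "closed"),
      n_phonemic_paraphasias = sum(.data$is_phon),
      n_semantic_paraphasias = sum(.data$is_sem),
      .groups = "drop"
    )

  utt <- tokens %>%
    distinct(.data$speaker, .data$task, .data$utt_id, .data$well_formed, .data$events)
  ev <- split_tags(utt$events)
  utt_stats <- utt %>%
    mutate(
      n_ap = vapply(ev, function(t) sum(t == "anomic_pause"), 0),
      n_cda_u = vapply(ev, function(t) sum(t == "cda"), 0)
    ) %>%
    group_by(.data$speaker) %>%
    summarise(
      n_correct_sentences = sum(.data$well_formed),
      n_anomic_pauses = sum(.data$n_ap),
      n_cda = sum(.data$n_cda_u),
      .groups = "drop"
    )

  out <- tok_stats %>%
    left_join(utt_stats, by = "speaker") %>%
    left_join(type_stats, by = "speaker") %>%
    mutate(
      across(
        c("n_noun_types", "n_verb_types", "n_adj_types", "n_open_types"),
        ~ dplyr::coalesce(.x, 0L)
      ),
      sdi_coverage = dplyr::coalesce(.data$sdi_coverage, 0),
      mean_occurrences = if_else(
        .data$n_open_types > 0,
        .data$n_open_tokens / .data$n_open_types,
        NA_real_
      )
    )
  out$mean_sdi <- if (sdi_weighting == "token") {
    token_sdi$mean_sdi_token[match(out$speaker, token_sdi$speaker)]
  } else {
    out$mean_sdi_type
  }
  out <- out %>%
    select(
      "speaker", "group", all_of(feature_order),
      "n_open_types", "sdi_coverage"
    ) %>%
    arrange(.data$speaker)
  class(out) <- c("feature_profile_tbl", class(out))
  out
}

#' Feature profile of a single transcript
#'
#' Convenience wrapper around [feature_profiles()] for one speaker's
#' transcript; errors if the token table is empty or mixes speakers.
#'
#' @inheritParams feature_profiles
#' @return One-row tibble.
#' @export
extract_features <- function(tokens, tax, freq_lex = NULL,
                             policy = "first_sense",
                             sdi_weighting = c("type", "token")) {
  tokens <- as_tibble(tokens)
  if (nrow(tokens) == 0L) abort("empty transcript")
  if (n_distinct(tokens$speaker) != 1L) {
    abort("extract_features() expects a single speaker; use feature_profiles()")
  }
  feature_profiles(tokens, tax, freq_lex, policy, sdi_weighting)
}

#' Fixed-order feature matrix
#'
#' Validates and orders a set of profiles into the canonical feature matrix:
#' one row per speaker, the thirteen features in reporting order. Duplicate
#' speakers are an error. Writable as tab-separated output.
#'
#' @param profiles Tibble from [feature_profiles()].
#' @return Tibble with columns speaker, group, the thirteen features.
#' @export
profile_table <- function(profiles) {
  profiles <- as_tibble(profiles)
  if (anyDuplicated(profiles$speaker)) {
    abort(paste0(
      "duplicate speaker id: ",
      profiles$speaker[duplicated(profiles$speaker)][1]
    ))
  }
  profiles %>% select("speaker", "group", all_of(feature_order))
}

#' Per-group feature means and standard deviations
#'
#' @param profiles Tibble from [feature_profiles()] (or any table with a
#'   `group` column and feature columns).
#' @param group Optional single group to summarise; error if absent.
#' @return Long tibble: group, feature (ordered factor), n, mean, sd
#'   (sample SD, n-1 denominator).
#' @export
group_summary <- function(profiles, group = NULL) {
  profiles <- as_tibble(profiles)
  if (!is.null(group)) {
    if (!group %in% profiles$group) abort(paste0("group not present: ", group))
    profiles <- profiles %>% filter(.data$group %in% !!group)
    if (nrow(profiles) < 2L) abort("need at least 2 profiles in the group")
  }
  feats <- intersect(feature_order, names(profiles))
  profiles %>%
    tidyr::pivot_longer(all_of(feats), names_to = "feature", values_to = "value") %>%
    mutate(feature = factor(.data$feature, levels = feature_order)) %>%
    group_by(.data$group, .data$feature) %>%
    summarise(
      n = sum(!is.na(.data$value)),
      mean = mean(.data$value, na.rm = TRUE),
      sd = stats::sd(.data$value, na.rm = TRUE),
      .groups = "drop"
    )
}

#' Feature-wise two-group comparison
#'
#' Mann-Whitney U test per feature between two groups of speakers, the
#' group-comparison table of the narrative-speech analysis.
#'
#' @param profiles Tibble from [feature_profiles()].
#' @param group1,group2 Group labels to contrast.
#' @return Tibble: feature, per-group means/SDs, `u` (the reported
#'   min(U1, U2)), `p`, and the exact/approximate method label.
#' @export
compare_groups <- function(profiles, group1, group2) {
  profiles <- as_tibble(profiles)
  for (g in c(group1, group2)) {
    if (!g %in% profiles$group) abort(paste0("group not present: ", g))
  }
  feats <- intersect(feature_order, names(profiles))
  purrr::map_dfr(feats, function(f) {
    x <- profiles[[f]][profiles$group == group1]
    y <- profiles[[f]][profiles$group == group2]
    x <- x[!is.na(x)]
    y <- y[!is.na(y)]
    if (!length(x) || !length(y)) {
      # feature undefined in a whole group (e.g. no frequency lexicon)
      return(tibble(
        feature = f, mean1 = NA_real_, sd1 = NA_real_,
        mean2 = NA_real_, sd2 = NA_real_,
        u = NA_real_, p = NA_real_, method = "not_computed"
      ))
    }
    mw <- suppressWarnings(mann_whitney_u(x, y))
    tibble(
      feature = f,
      mean1 = mean(x), sd1 = stats::sd(x),
      mean2 = mean(y), sd2 = stats::sd(y),
      u = mw$u_reported, p = mw$p_two_sided, method = mw$method
    )
  }) %>%
    mutate(feature = factor(.data$feature, levels = feature_order))
}

#' Boxplots of a feature by group
#'
#' @param object A `feature_profile_tbl` from [feature_profiles()].
#' @param feature Feature column to plot (default `mean_sdi`).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot feature_profile_tbl
#' @export
autoplot.feature_profile_tbl <- function(object, feature = "mean_sdi", ...) {
  ggplot2::ggplot(
    object,
    ggplot2::aes(x = .data$group, y = .data[[feature]], fill = .data$group)
  ) +
    ggplot2::geom_boxplot(outlier.shape = NA, alpha = 0.6) +
    ggplot2::geom_jitter(width = 0.1, height = 0, size = 1.5) +
    ggplot2::labs(x = NULL, y = feature) +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal()
}
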