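#' Annotation vocabularies for narrative transcripts
#'
#' Word classes, error tags, utterance events and elicitation tasks accepted
#' by the transcript reader. Annotation arrives pre-coded (the coding of word
#' class, speech errors and sentence well-formedness is an input, not an
#' inference made here).
#' @name transcript-vocab
#' @keywords internal
NULL

word_class_levels <- c("noun", "verb", "adjective", "adverb", "closed", "filler")
error_tag_levels <- c("phonemic_paraphasia", "semantic_paraphasia", "false_start")
event_levels <- c("anomic_pause", "cda")
task_levels <- c("cookie_theft", "picnic", "illness", "typical_day", "conversation")
open_classes <- c("noun", "verb", "adjective", "adverb")

transcript_cols <- c(
  "speaker", "group", "task", "utt_id", "well_formed", "events",
  "surface", "lemma", "word_class", "error_tags"
)

split_tags <- function(x) {
  lapply(strsplit(x, ",", fixed = TRUE), function(t) t[t != "."])
}

validate_transcript_tokens <- function(d, lineno = NULL) {
  where <- function(i) {
    if (is.null(lineno)) "" else paste0(" (line ", lineno[i], ")")
  }
  bad <- which(!d$word_class %in% word_class_levels)
  if (length(bad)) {
    abort(paste0("unknown word_class '", d$word_class[bad[1]], "'", where(bad[1])))
  }
  bad <- which(!d$task %in% task_levels)
  if (length(bad)) {
    abort(paste0("unknown task '", d$task[bad[1]], "'", where(bad[1])))
  }
  tags <- split_tags(d$error_tags)
  bad <- which(vapply(tags, function(t) any(!t %in% error_tag_levels), TRUE))
  if (length(bad)) {
    abort(paste0("unknown error tag in '", d$error_tags[bad[1]], "'", where(bad[1])))
  }
  evs <- split_tags(d$events)
  bad <- which(vapply(evs, function(t) any(!t %in% event_levels), TRUE))
  if (length(bad)) {
    abort(paste0("unknown utterance event in '", d$events[bad[1]], "'", where(bad[1])))
  }
  bad <- which(is.na(d$speaker) | d$speaker == "")
  if (length(bad)) abort(paste0("empty speaker id", where(bad[1])))
  invisible(d)
}

finalize_tokens <- function(d) {
  d %>%
    mutate(
      lemma = tolower(.data$lemma),
      excluded = .data$word_class == "filler" |
        vapply(split_tags(.data$error_tags), function(t) "false_start" %in% t, TRUE)
    )
}

#' Read annotated narrative transcripts
#'
#' One row per token, tab-separated, UTF-8, with header
#' `speaker group task utt_id well_formed events surface lemma word_class
#' error_tags`. `error_tags` and `events` are comma-joined or `.` for none;
#' utterance-level events appear on the utterance's first row only and are
#' propagated to every token row in memory. Lemmas are case-folded; surface
#' forms are kept verbatim. A derived logical column `excluded` marks
#' fillers and false starts, which do not enter lexical counts.
#'
#' @param path Transcript file path.
#' @return Tibble of tokens with the dialect columns plus `excluded`,
#'   ordered as in the file.
#' @export
read_transcripts <- function(path) {
  if (!file.exists(path)) abort(paste0("transcript file not found: ", path))
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  if (!length(lines)) abort("empty transcript file")
  hdr <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (!identical(hdr, transcript_cols)) {
    abort(paste0(
      "transcript header mismatch; expected: ",
      paste(transcript_cols, collapse = " ")
    ))
  }
  body <- lines[-1]
  lineno <- seq_along(body) + 1L
  keep <- body != ""
  body <- body[keep]
  lineno <- lineno[keep]
  if (!length(body)) {
    d <- tibble(!!!stats::setNames(rep(list(character()), 10), transcript_cols))
    d$well_formed <- logical()
    d$utt_id <- integer()
    return(finalize_tokens(d))
  }
  parts <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 10L)) {
    i <- which(nf != 10L)[1]
    abort(paste0("expected 10 tab-separated fields, got ", nf[i], " (line ", lineno[i], ")"))
  }
  m <- matrix(unlist(parts), ncol = 10, byrow = TRUE)
  d <- as_tibble(stats::setNames(as.data.frame(m, stringsAsFactors = FALSE), transcript_cols))
  if (any(!d$well_formed %in% c("0", "1"))) {
    i <- which(!d$well_formed %in% c("0", "1"))[1]
    abort(paste0("well_formed must be 0 or 1 (line ", lineno[i], ")"))
  }
  d$well_formed <- d$well_formed == "1"
  d$utt_id <- as.integer(d$utt_id)
  validate_transcript_tokens(d, lineno)
  # events are written on the first token row of an utterance only
  d <- d %>%
    group_by(.data$speaker, .data$task, .data$utt_id) %>%
    mutate(events = first(.data$events)) %>%
    ungroup()
  finalize_tokens(d)
}

#' Write transcripts in the canonical dialect
#'
#' Inverse of [read_transcripts()]: tokens are written in row order, one per
#' line, with utterance events emitted on the first row of each utterance
#' only. `write_transcripts()` then [read_transcripts()] is the identity on
#' the stored columns, and re-writing reproduces identical bytes.
#'
#' @param tokens Token tibble as returned by [read_transcripts()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_transcripts <- function(tokens, path) {
  tokens <- as_tibble(tokens)
  d <- tokens %>%
    group_by(.data$speaker, .data$task, .data$utt_id) %>%
    mutate(.first = row_number() == 1L) %>%
    ungroup() %>%
    mutate(events = if_else(.data$.first, .data$events, "."))
  lines <- c(
    paste(transcript_cols, collapse = "\t"),
    if (nrow(d)) {
      paste(
        d$speaker, d$group, d$task, d$utt_id,
        as.integer(d$well_formed), d$events,
        d$surface, d$lemma, d$word_class, d$error_tags,
        sep = "\t"
      )
    }
  )
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, useBytes = TRUE)
  invisible(path)
}

#' Merge one speaker's transcripts across tasks
#'
#' Concatenates a speaker's utterances in the canonical task order
#' (cookie_theft, picnic, illness, typical_day, conversation), preserving
#' token order within each task. Feature profiles are computed per speaker
#' across all elicitation contexts.
#'
#' @param tokens Token tibble (possibly several tasks).
#' @param speaker_id The speaker; all rows must belong to them.
#' @return Token tibble reordered by task.
#' @export
merge_speaker <- function(tokens, speaker_id) {
  tokens <- as_tibble(tokens)
  ids <- unique(tokens$speaker)
  if (!setequal(ids, speaker_id)) {
    abort(paste0(
      "mixed speaker ids: expected '", speaker_id, "', found: ",
      paste(ids, collapse = ", ")
    ))
  }
  tokens %>%
    arrange(factor(.data$task, levels = task_levels)) %>%
    ungroup()
}
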