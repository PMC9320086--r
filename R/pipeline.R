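#' Run the feature-extraction stage
#'
#' Reads a taxonomy, transcripts and (optionally) a frequency lexicon,
#' derives per-speaker feature profiles, and writes the fixed-order feature
#' matrix plus a coverage log. Inputs are checked up front so a failure
#' leaves no partial outputs. Reruns on identical inputs produce identical
#' output bytes.
#'
#' @param taxonomy,transcripts,freq Input file paths (`freq` may be NULL).
#' @param out_dir Output directory (created if needed).
#' @param policy,sdi_weighting Passed to [feature_profiles()].
#' @return Invisibly, a list with the `profiles` tibble, the `coverage`
#'   report, and output `paths`.
#' @export
run_features <- function(taxonomy, transcripts, freq = NULL, out_dir,
                         policy = "first_sense", sdi_weighting = "type") {
  for (p in c(taxonomy, transcripts, freq)) {
    if (!file.exists(p)) abort(paste0("input not found: ", p))
  }
  tax <- read_taxonomy(taxonomy)
  tokens <- read_transcripts(transcripts)
  lex <- if (!is.null(freq)) read_frequency_lexicon(freq)
  profiles <- feature_profiles(tokens, tax, lex,
    policy = policy, sdi_weighting = sdi_weighting
  )
  words <- tokens %>%
    filter(!.data$excluded, .data$word_class %in% open_classes) %>%
    distinct(.data$lemma, pos = .data$word_class)
  cov <- coverage_report(words, tax)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    features = file.path(out_dir, "feature-profiles.tsv"),
    coverage = file.path(out_dir, "coverage.tsv")
  )
  write_tsv_bytes(profile_table(profiles), paths[["features"]])
  write_tsv_bytes(cov$by_pos, paths[["coverage"]])
  message(
    "scored ", nrow(profiles), " speaker(s); taxonomy source: ",
    tax$meta$source %||% "unknown", "; sense policy: ", policy,
    "; overall SDI coverage: ", formatC(cov$coverage, digits = 3, format = "f")
  )
  invisible(list(profiles = profiles, coverage = cov, paths = paths))
}

#' Run the full analysis pipeline
#'
#' End-to-end: feature profiles per speaker, a feature-wise comparison of
#' the two clinical groups, per-group regional thickness contrasts against
#' controls, and FDR-corrected correlations between mean SDI and
#' semantic-network thickness on the pooled clinical sample. Writes four
#' result tables plus a machine-readable run manifest (input checksums,
#' config echo, package version); identical inputs and config give
#' identical outputs.
#'
#' @param taxonomy,transcripts,freq,thickness Input file paths (`freq`
#'   optional).
#' @param out_dir Output directory.
#' @param q FDR level in (0, 1).
#' @param policy,sdi_weighting Passed to [feature_profiles()].
#' @param control_group Label of the control group in the thickness table.
#' @return Invisibly, a list with `profiles`, `comparison`, `contrasts`
#'   (per clinical group), `correlations`, and `paths`.
#' @export
run_full <- function(taxonomy, transcripts, freq = NULL, thickness,
                     out_dir, q = 0.05,
                     policy = "first_sense", sdi_weighting = "type",
                     control_group = "HC") {
  if (q <= 0 || q >= 1) abort("q must lie in (0, 1)")
  for (p in c(taxonomy, transcripts, freq, thickness)) {
    if (!file.exists(p)) abort(paste0("input not found: ", p))
  }
  tax <- read_taxonomy(taxonomy)
  tokens <- read_transcripts(transcripts)
  lex <- if (!is.null(freq)) read_frequency_lexicon(freq)
  tt <- read_thickness(thickness)

  profiles <- feature_profiles(tokens, tax, lex,
    policy = policy, sdi_weighting = sdi_weighting
  )
  groups <- setdiff(unique(profiles$group), control_group)
  if (length(groups) < 2L) abort("need at least 2 clinical groups in the transcripts")

  comparison <- compare_groups(profiles, groups[1], groups[2])

  contrasts <- list()
  if (control_group %in% tt$group) {
    for (g in intersect(groups, unique(tt$group))) {
      contrasts[[g]] <- group_thickness_contrast(tt, g, control_group, q = q)
    }
  }

  missing_subj <- setdiff(profiles$speaker, unique(tt$subject))
  if (length(missing_subj)) {
    abort(paste0(
      "speaker(s) without thickness values: ",
      paste(missing_subj, collapse = ", ")
    ))
  }
  correlations <- correlate_sdi_thickness(profiles, tt, q = q)

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    features = file.path(out_dir, "feature-profiles.tsv"),
    comparison = file.path(out_dir, "feature-comparison.tsv"),
    correlations = file.path(out_dir, "sdi-thickness-correlations.tsv"),
    manifest = file.path(out_dir, "manifest.json")
  )
  write_tsv_bytes(profile_table(profiles), paths[["features"]])
  write_tsv_bytes(comparison, paths[["comparison"]])
  write_tsv_bytes(correlations, paths[["correlations"]])
  for (g in names(contrasts)) {
    p <- file.path(out_dir, paste0("thickness-contrast-", g, ".tsv"))
    write_tsv_bytes(contrasts[[g]], p)
    paths[[paste0("contrast_", g)]] <- p
  }

  inputs <- c(taxonomy = taxonomy, transcripts = transcripts, thickness = thickness)
  if (!is.null(freq)) inputs <- c(inputs, freq = freq)
  manifest <- list(
    package = "semdepth",
    version = as.character(utils::packageVersion("semdepth")),
    config = list(
      q = q, policy = policy, sdi_weighting = sdi_weighting,
      control_group = control_group
    ),
    inputs = as.list(tools::md5sum(inputs)),
    n_speakers = nrow(profiles),
    groups = as.list(table(profiles$group))
  )
  jsonlite::write_json(manifest, paths[["manifest"]],
    auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  invisible(list(
    profiles = profiles, comparison = comparison,
    contrasts = contrasts, correlations = correlations, paths = paths
  ))
}

# deterministic TSV writer (fixed number formatting, LF, UTF-8 bytes)
write_tsv_bytes <- function(d, path) {
  d <- as.data.frame(d)
  for (j in seq_along(d)) {
    if (is.factor(d[[j]])) d[[j]] <- as.character(d[[j]])
    if (is.numeric(d[[j]])) {
      d[[j]] <- formatC(d[[j]], digits = 10, format = "g")
    }
    if (is.logical(d[[j]])) d[[j]] <- as.integer(d[[j]])
    if (is.list(d[[j]])) d[[j]] <- vapply(d[[j]], paste, "", collapse = "|")
  }
  lines <- c(
    paste(names(d), collapse = "\t"),
    if (nrow(d)) do.call(paste, c(unname(d), sep = "\t"))
  )
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, useBytes = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
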