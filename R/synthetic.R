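#' Synthetic-cohort configuration
#'
#' Bundles every parameter of the synthetic generators. Defaults emulate the
#' study conditions of the motivating clinical design: 6 semantic-variant
#' (svPPA) and 16 logopenic-variant (lvPPA) speakers plus 30 healthy
#' controls (thickness only — controls undergo no speech assessment);
#' group-conditioned lexical depth preference; token, error and event counts
#' at the reported group means; regional thickness baselines at the reported
#' per-group means/SDs; and a planted linear association between mean SDI
#' and thickness in the semantic-network ROIs that the clinical study found
#' significant.
#'
#' The lexical-choice model samples open-class lemmas with probability
#' proportional to `exp(theta * depth)`: more negative `theta` prefers
#' shallower (more generic) words, the hallmark of svPPA speech. Speaker
#' heterogeneity comes from per-speaker `theta_i ~ N(theta_g, theta_sd)`.
#'
#' @param seed Master seed; everything downstream derives from it, so equal
#'   seeds give byte-identical generated files.
#' @param n_sv,n_lv,n_hc Group sizes.
#' @param theta Named depth-preference weights for `svPPA` and `lvPPA`.
#' @param theta_sd Between-speaker SD of theta.
#' @param open_tokens,closed_tokens Named per-group mean token counts
#'   (negative binomial, dispersion `token_size`).
#' @param token_size Negative-binomial size (inverse dispersion).
#' @param rates Per-group Poisson means for phonemic/semantic paraphasias,
#'   anomic pauses and conduites d'approche, plus the well-formed-sentence
#'   probability `wf_prob`.
#' @param utt_len Mean utterance length in tokens (Poisson + 1).
#' @param adj_prop Proportion of open tokens drawn as out-of-taxonomy
#'   adjectives (exercises partial SDI coverage).
#' @param thickness_params Per-region baselines: tibble with columns lobe,
#'   region, hemisphere, mean_/sd_ per group (default: the packaged table).
#' @param assoc Planted SDI-thickness association: list with `rois` (tibble
#'   of region/hemisphere) and `r_target`, or `NULL` for no association
#'   (all betas zero).
#' @return List of class `cohort_config`.
#' @export
cohort_config <- function(seed = 1L,
                          n_sv = 6L, n_lv = 16L, n_hc = 30L,
                          theta = c(svPPA = -1.07, lvPPA = -0.815),
                          theta_sd = 0.10,
                          open_tokens = c(svPPA = 286, lvPPA = 162),
                          closed_tokens = c(svPPA = 349, lvPPA = 271),
                          token_size = 12,
                          rates = list(
                            svPPA = c(
                              phonemic = 1.50, semantic = 3.50,
                              anomic = 6.83, cda = 6.83, wf_prob = 0.90
                            ),
                            lvPPA = c(
                              phonemic = 4.88, semantic = 2.50,
                              anomic = 8.63, cda = 7.19, wf_prob = 0.55
                            )
                          ),
                          utt_len = 4.4,
                          adj_prop = 0.08,
                          thickness_params = NULL,
                          assoc = list(
                            rois = tibble(
                              region = c(
                                "entorhinal", "middletemporal", "parahippocampal",
                                "superiortemporal", "temporalpole",
                                "entorhinal", "parahippocampal", "temporalpole"
                              ),
                              hemisphere = c(rep("left", 5), rep("right", 3))
                            ),
                            r_target = 0.66
                          )) {
  if (any(c(n_sv, n_lv, n_hc) < 0) || n_sv + n_lv < 2) {
    abort("invalid group sizes")
  }
  if (theta_sd < 0 || token_size <= 0) abort("dispersion parameters must be positive")
  if (is.null(thickness_params)) thickness_params <- thickness_params()
  structure(
    list(
      seed = as.integer(seed), n_sv = n_sv, n_lv = n_lv, n_hc = n_hc,
      theta = theta, theta_sd = theta_sd,
      open_tokens = open_tokens, closed_tokens = closed_tokens,
      token_size = token_size, rates = rates, utt_len = utt_len,
      adj_prop = adj_prop, thickness_params = thickness_params,
      assoc = assoc
    ),
    class = "cohort_config"
  )
}

# fixed per-stage offsets keep the generator substreams independent under
# one master seed; all stay far below .Machine$integer.max
stage_seed <- function(cfg_seed, stage) {
  offs <- c(taxonomy = 11L, lexicon = 23L, transcripts = 37L, thickness = 53L)
  (cfg_seed %% 1000003L) * 1000L + offs[[stage]]
}

#' Generate a synthetic hypernym taxonomy
#'
#' Builds complete `branching`-ary is-a trees (one per root) of the given
#' depth, with one unique synthetic lemma per synset. Structure is fully
#' determined by the parameters; the seed is recorded and reserved for
#' lemma-level randomisation, so equal calls are byte-identical.
#'
#' @param seed Seed (recorded in `meta`).
#' @param n_roots Number of root synsets.
#' @param branching Children per synset.
#' @param max_depth Tree depth (>= 1); a depth-`d` tree holds
#'   `(branching^(d+1) - 1) / (branching - 1)` synsets per root.
#' @param pos Word class of the tree(s).
#' @return A [taxonomy()].
#' @export
gen_taxonomy <- function(seed = 1L, n_roots = 1L, branching = 2L,
                         max_depth = 8L, pos = "noun") {
  if (max_depth < 1L || branching < 1L || n_roots < 1L) {
    abort("gen_taxonomy needs max_depth >= 1, branching >= 1, n_roots >= 1")
  }
  pos <- match.arg(pos, tax_pos_levels)
  pfx <- substr(pos, 1, 1)
  syn <- list()
  edg <- list()
  counter <- 0L
  for (r in seq_len(n_roots)) {
    # breadth-first construction of one complete tree
    ids_prev <- character()
    for (d in 0:max_depth) {
      n_level <- if (d == 0L) 1L else length(ids_prev) * branching
      ids <- sprintf("%s%06d", pfx, counter + seq_len(n_level))
      counter <- counter + n_level
      syn[[length(syn) + 1L]] <- tibble(
        id = ids, pos = pos,
        lemmas = paste0(pos, "_", sub("^.", "", ids)),
        gloss = NA_character_
      )
      if (d > 0L) {
        edg[[length(edg) + 1L]] <- tibble(
          hyponym = ids,
          hypernym = rep(ids_prev, each = branching)
        )
      }
      ids_prev <- ids
    }
  }
  taxonomy(
    bind_rows(syn), bind_rows(edg),
    meta = list(
      source = "synthetic",
      seed = seed, branching = branching, max_depth = max_depth
    )
  )
}

# (lemma, pos, depth) sampling universe of a taxonomy, first-sense depths
open_lemma_pool <- function(tax) {
  tax$lemma_index %>%
    filter(.data$sense_rank == 1L) %>%
    mutate(depth = synset_depth(tax, .data$synset_id)) %>%
    select("lemma", "pos", "depth")
}

synthetic_closed_words <- paste0("fw", sprintf("%02d", 1:40))
synthetic_adjectives <- paste0("adj", sprintf("%02d", 1:30))
synthetic_fillers <- c("uh", "um", "eh")

#' Generate annotated synthetic transcripts
#'
#' One transcript set per clinical speaker (controls produce no speech).
#' Open-class lemmas are sampled with probability proportional to
#' `exp(theta_i * depth)`; groups with lower theta produce stochastically
#' shallower (more generic) vocabularies. Closed-class tokens, fillers,
#' false starts, paraphasia tags and utterance events are drawn at the
#' configured per-group rates; utterances are split across the five
#' elicitation tasks.
#'
#' @param cfg A [cohort_config()].
#' @param tax A non-empty [taxonomy()].
#' @return Token tibble in [read_transcripts()] layout.
#' @export
gen_transcripts <- function(cfg, tax) {
  stopifnot(inherits(cfg, "cohort_config"), inherits(tax, "taxonomy"))
  pool <- open_lemma_pool(tax)
  if (nrow(pool) == 0L) abort("taxonomy has no lemmas to sample")
  set.seed(stage_seed(cfg$seed, "transcripts"))

  speakers <- tibble(
    speaker = c(
      sprintf("sv%02d", seq_len(cfg$n_sv)),
      sprintf("lv%02d", seq_len(cfg$n_lv))
    ),
    group = c(rep("svPPA", cfg$n_sv), rep("lvPPA", cfg$n_lv))
  )

  res <- vector("list", nrow(speakers))
  for (i in seq_len(nrow(speakers))) {
    g <- speakers$group[i]
    rates <- cfg$rates[[g]]
    theta_i <- stats::rnorm(1, cfg$theta[[g]], cfg$theta_sd)
    n_open <- max(30L, stats::rnbinom(1, mu = cfg$open_tokens[[g]], size = cfg$token_size))
    n_closed <- max(20L, stats::rnbinom(1, mu = cfg$closed_tokens[[g]], size = cfg$token_size))
    n_adj <- stats::rbinom(1, n_open, cfg$adj_prop)
    n_tax <- n_open - n_adj

    w <- exp(theta_i * pool$depth)
    idx <- sample.int(nrow(pool), n_tax, replace = TRUE, prob = w)
    open_lem <- pool$lemma[idx]
    open_cls <- pool$pos[idx]
    if (n_adj > 0) {
      open_lem <- c(open_lem, sample(synthetic_adjectives, n_adj, replace = TRUE))
      open_cls <- c(open_cls, rep("adjective", n_adj))
    }
    closed_lem <- sample(synthetic_closed_words, n_closed,
      replace = TRUE,
      prob = 1 / seq_along(synthetic_closed_words)
    )
    n_fill <- stats::rpois(1, 5)
    n_fs <- stats::rpois(1, 3)
    fill_lem <- sample(synthetic_fillers, n_fill, replace = TRUE)
    fs_lem <- sample(pool$lemma, n_fs, replace = TRUE)

    lemma <- c(open_lem, closed_lem, fill_lem, fs_lem)
    wclass <- c(
      open_cls, rep("closed", n_closed),
      rep("filler", n_fill), rep("noun", n_fs)
    )
    tags <- rep(".", length(lemma))
    tags[length(open_lem) + n_closed + n_fill + seq_len(n_fs)] <- "false_start"

    # paraphasia tags land on open-class tokens
    n_phon <- min(stats::rpois(1, rates[["phonemic"]]), length(open_lem))
    n_sem <- min(stats::rpois(1, rates[["semantic"]]), length(open_lem))
    err_idx <- sample.int(length(open_lem), min(length(open_lem), n_phon + n_sem))
    if (n_phon > 0) tags[err_idx[seq_len(n_phon)]] <- "phonemic_paraphasia"
    if (n_sem > 0 && length(err_idx) > n_phon) {
      tags[err_idx[n_phon + seq_len(length(err_idx) - n_phon)]] <- "semantic_paraphasia"
    }

    ord <- sample.int(length(lemma))
    lemma <- lemma[ord]
    wclass <- wclass[ord]
    tags <- tags[ord]

    # chunk the token stream into utterances
    n_tok <- length(lemma)
    utt_len <- pmax(1L, stats::rpois(ceiling(n_tok / max(1, cfg$utt_len)) + 10L, cfg$utt_len))
    while (sum(utt_len) < n_tok) {
      utt_len <- c(utt_len, pmax(1L, stats::rpois(10L, cfg$utt_len)))
    }
    utt_id <- rep(seq_along(utt_len), utt_len)[seq_len(n_tok)]
    n_utt <- max(utt_id)
    wf <- stats::runif(n_utt) < rates[["wf_prob"]]
    ev_ap <- tabulate(sample.int(n_utt, stats::rpois(1, rates[["anomic"]]), replace = TRUE), n_utt)
    ev_cda <- tabulate(sample.int(n_utt, stats::rpois(1, rates[["cda"]]), replace = TRUE), n_utt)
    events <- mapply(function(a, k) {
      s <- c(rep("anomic_pause", a), rep("cda", k))
      if (length(s)) paste(s, collapse = ",") else "."
    }, ev_ap, ev_cda)

    # spread utterances over the five tasks in contiguous blocks
    task_of_utt <- task_levels[pmin(5L, ceiling(seq_len(n_utt) / (n_utt / 5)))]

    res[[i]] <- tibble(
      speaker = speakers$speaker[i],
      group = g,
      task = task_of_utt[utt_id],
      utt_id = utt_id,
      well_formed = wf[utt_id],
      events = unname(events[utt_id]),
      surface = lemma,
      lemma = lemma,
      word_class = wclass,
      error_tags = tags
    )
  }
  finalize_tokens(bind_rows(res))
}

#' Generate a synthetic frequency lexicon
#'
#' Zipf-like frequencies (per million) over every lemma of the taxonomy
#' plus the synthetic closed-class/adjective inventories.
#'
#' @param cfg A [cohort_config()].
#' @param tax A [taxonomy()].
#' @return Frequency-lexicon tibble (`lemma`, `pos`, `fpm`).
#' @export
gen_frequency_lexicon <- function(cfg, tax) {
  set.seed(stage_seed(cfg$seed, "lexicon"))
  pool <- open_lemma_pool(tax)
  lex <- bind_rows(
    pool %>% select("lemma", "pos"),
    tibble(lemma = synthetic_adjectives, pos = "adjective"),
    tibble(lemma = synthetic_closed_words, pos = "closed")
  )
  rank <- sample.int(nrow(lex))
  lex$fpm <- round(2e4 / rank^1.05, 2)
  lex
}

#' Generate a synthetic cortical-thickness table
#'
#' Clinical subjects come from `profiles`; healthy controls are appended.
#' Baselines are the per-group regional means/SDs in
#' `cfg$thickness_params`. When `cfg$assoc` is set, the designated ROIs of
#' clinical subjects are drawn as
#' `pooled_baseline + beta * (mean_sdi - cohort mean) + noise`, with `beta =
#' r_target * sd_roi / sd_sdi` and noise SD `sd_roi * sqrt(1 - r_target^2)`,
#' so the ROI keeps its configured SD and carries a planted correlation of
#' exactly `r_target` with mean SDI. With `assoc = NULL` every region is an
#' independent group-mean draw (no SDI dependence). Controls always draw
#' from the control baselines.
#'
#' @param cfg A [cohort_config()].
#' @param profiles Feature profiles of the clinical speakers (needs
#'   `speaker`, `group`, `mean_sdi`).
#' @return A `thickness_tbl`.
#' @export
gen_thickness <- function(cfg, profiles) {
  stopifnot(inherits(cfg, "cohort_config"))
  profiles <- as_tibble(profiles)
  if (!all(c("speaker", "group", "mean_sdi") %in% names(profiles))) {
    abort("profiles need speaker, group and mean_sdi columns")
  }
  set.seed(stage_seed(cfg$seed, "thickness"))
  pars <- cfg$thickness_params
  subjects <- bind_rows(
    profiles %>% select(subject = "speaker", "group"),
    tibble(subject = sprintf("hc%02d", seq_len(cfg$n_hc)), group = "HC")
  )
  grid <- tidyr::crossing(subjects, pars %>% select("region", "hemisphere"))
  grid <- grid %>%
    left_join(pars, by = c("region", "hemisphere")) %>%
    mutate(
      mu = dplyr::case_when(
        group == "svPPA" ~ .data$mean_svPPA,
        group == "lvPPA" ~ .data$mean_lvPPA,
        TRUE ~ .data$mean_HC
      ),
      sdv = dplyr::case_when(
        group == "svPPA" ~ .data$sd_svPPA,
        group == "lvPPA" ~ .data$sd_lvPPA,
        TRUE ~ .data$sd_HC
      )
    )

  if (!is.null(cfg$assoc)) {
    sdi_bar <- mean(profiles$mean_sdi)
    sdi_sd <- stats::sd(profiles$mean_sdi)
    if (!is.finite(sdi_sd) || sdi_sd == 0) {
      abort("cannot plant an association: mean SDI has zero variance")
    }
    r <- cfg$assoc$r_target
    n_cl <- c(svPPA = cfg$n_sv, lvPPA = cfg$n_lv)
    # pooled clinical baseline per designated ROI
    des <- cfg$assoc$rois %>% mutate(.designated = TRUE)
    grid <- grid %>%
      left_join(des, by = c("region", "hemisphere")) %>%
      mutate(.designated = !is.na(.data$.designated) & .data$group != "HC") %>%
      left_join(
        profiles %>% select(subject = "speaker", "mean_sdi"),
        by = "subject"
      ) %>%
      mutate(
        # one pooled clinical baseline and scale per designated ROI, so the
        # planted slope is common to both clinical groups and the pooled
        # correlation equals r exactly
        mu_pool = (cfg$n_sv * .data$mean_svPPA + cfg$n_lv * .data$mean_lvPPA) /
          (cfg$n_sv + cfg$n_lv),
        sd_pool = (cfg$n_sv * .data$sd_svPPA + cfg$n_lv * .data$sd_lvPPA) /
          (cfg$n_sv + cfg$n_lv),
        mu = if_else(
          .data$.designated,
          .data$mu_pool + (r * .data$sd_pool / sdi_sd) * (.data$mean_sdi - sdi_bar),
          .data$mu
        ),
        sdv = if_else(.data$.designated, .data$sd_pool * sqrt(1 - r^2), .data$sdv)
      )
  }

  out <- grid %>%
    mutate(thickness = stats::rnorm(n(), .data$mu, .data$sdv)) %>%
    select("subject", "group", "region", "hemisphere", "thickness")
  class(out) <- c("thickness_tbl", class(out))
  out
}

#' Generate a complete synthetic cohort
#'
#' Runs every generator under one master seed: taxonomy, frequency lexicon,
#' clinical transcripts, per-speaker feature profiles, and a thickness table
#' whose designated ROIs carry the configured planted association with mean
#' SDI. Optionally writes the four input files (plus a config echo) in the
#' package's file dialects; equal seeds give byte-identical files.
#'
#' @param cfg A [cohort_config()].
#' @param out_dir Optional directory to write `taxonomy.tsv`,
#'   `transcripts.tsv`, `frequency-lexicon.tsv`, `thickness.tsv` and
#'   `config.txt` into.
#' @param policy,sdi_weighting Passed to [feature_profiles()].
#' @return List: `taxonomy`, `lexicon`, `tokens`, `profiles`, `thickness`,
#'   `config`, and `paths` when written.
#' @export
simulate_cohort <- function(cfg = cohort_config(), out_dir = NULL,
                            policy = "first_sense", sdi_weighting = "type") {
  stopifnot(inherits(cfg, "cohort_config"))
  tax <- gen_taxonomy(seed = stage_seed(cfg$seed, "taxonomy"))
  vtax <- gen_taxonomy(
    seed = stage_seed(cfg$seed, "taxonomy"),
    branching = 2L, max_depth = 5L, pos = "verb"
  )
  tax <- merge_taxonomies(tax, vtax)
  lex <- gen_frequency_lexicon(cfg, tax)
  tokens <- gen_transcripts(cfg, tax)
  profiles <- feature_profiles(tokens, tax, lex,
    policy = policy, sdi_weighting = sdi_weighting
  )
  thick <- gen_thickness(cfg, profiles)
  out <- list(
    taxonomy = tax, lexicon = lex, tokens = tokens,
    profiles = profiles, thickness = thick, config = cfg
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- c(
      taxonomy = file.path(out_dir, "taxonomy.tsv"),
      transcripts = file.path(out_dir, "transcripts.tsv"),
      lexicon = file.path(out_dir, "frequency-lexicon.tsv"),
      thickness = file.path(out_dir, "thickness.tsv"),
      config = file.path(out_dir, "config.txt")
    )
    write_taxonomy(tax, paths[["taxonomy"]])
    write_transcripts(tokens, paths[["transcripts"]])
    write_frequency_lexicon(lex, paths[["lexicon"]])
    write_thickness(thick, paths[["thickness"]])
    writeLines(config_echo(cfg), paths[["config"]])
    out$paths <- paths
  }
  out
}

#' Merge taxonomies of disjoint synset sets
#' @param ... `taxonomy` objects with pairwise-disjoint synset ids.
#' @return A single [taxonomy()].
#' @export
merge_taxonomies <- function(...) {
  parts <- list(...)
  taxonomy(
    bind_rows(lapply(parts, function(t) {
      s <- t$synsets
      s$lemmas <- s$lemmas
      s[, c("id", "pos", "lemmas", "gloss")]
    })),
    bind_rows(lapply(parts, function(t) t$edges)),
    meta = parts[[1]]$meta
  )
}

# flat key: value echo of a cohort config, for output headers
config_echo <- function(cfg) {
  flat <- c(
    seed = cfg$seed, n_sv = cfg$n_sv, n_lv = cfg$n_lv, n_hc = cfg$n_hc,
    theta_svPPA = cfg$theta[["svPPA"]], theta_lvPPA = cfg$theta[["lvPPA"]],
    theta_sd = cfg$theta_sd,
    open_tokens_svPPA = cfg$open_tokens[["svPPA"]],
    open_tokens_lvPPA = cfg$open_tokens[["lvPPA"]],
    token_size = cfg$token_size,
    assoc_r = if (is.null(cfg$assoc)) 0 else cfg$assoc$r_target
  )
  paste0(names(flat), ": ", unname(flat))
}
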