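#' @import rlang
#' @importFrom dplyr %>% filter mutate select arrange group_by summarise ungroup
#'   left_join inner_join anti_join bind_rows distinct n n_distinct row_number
#'   first across all_of pull rename count slice if_else
#' @importFrom tibble tibble as_tibble
#' @importFrom rlang .data abort warn
NULL

#' Word classes carrying hypernym structure
#' @keywords internal
tax_pos_levels <- c("noun", "verb", "adjective", "adverb")

#' Construct a validated hypernym taxonomy
#'
#' A taxonomy is a directed acyclic "is-a" graph over synsets (sets of
#' synonymous lemmas), with edges pointing from hyponym (more specific) to
#' hypernym (more general). Synsets with no hypernym are roots; each word
#' class (noun, verb, ...) may have its own root(s). Depths — the basis of
#' the Semantic Depth Index — are the minimum number of hypernym edges from
#' a synset to any root of its word class, computed once at construction.
#'
#' @param synsets Data frame with columns `id` (unique character), `pos`
#'   (one of noun/verb/adjective/adverb), `lemmas` (list column of character
#'   vectors, or a character column with lemmas joined by `|`), and
#'   optionally `gloss`.
#' @param edges Data frame with columns `hyponym`, `hypernym` (synset ids).
#' @param meta Optional named list of provenance metadata (e.g. a source
#'   version string), echoed into outputs.
#' @return An object of class `taxonomy`: a list with tibbles `synsets`
#'   (including a `depth` column), `edges`, `lemma_index` (lemma, pos,
#'   synset_id, sense_rank), the `roots` ids, and `meta`.
#' @examples
#' tax <- taxonomy(
#'   synsets = tibble::tibble(
#'     id = c("n1", "n2"), pos = "noun",
#'     lemmas = list("entity", c("animal", "beast"))
#'   ),
#'   edges = tibble::tibble(hyponym = "n2", hypernym = "n1")
#' )
#' synset_depth(tax, "n2")
#' @export
taxonomy <- function(synsets, edges = NULL, meta = list()) {
  synsets <- as_tibble(synsets)
  if (!all(c("id", "pos") %in% names(synsets))) {
    abort("`synsets` needs columns `id` and `pos`")
  }
  if (!"gloss" %in% names(synsets)) synsets$gloss <- NA_character_
  if (!"lemmas" %in% names(synsets)) {
    abort("`synsets` needs a `lemmas` column")
  }
  if (is.character(synsets$lemmas)) {
    synsets$lemmas <- strsplit(synsets$lemmas, "|", fixed = TRUE)
  }
  synsets$lemmas <- lapply(synsets$lemmas, function(x) tolower(trimws(x)))
  if (anyDuplicated(synsets$id)) {
    abort(paste0("duplicate synset id: ", synsets$id[duplicated(synsets$id)][1]))
  }
  bad_pos <- setdiff(unique(synsets$pos), tax_pos_levels)
  if (length(bad_pos)) {
    abort(paste0("unknown word class: ", bad_pos[1]))
  }
  if (any(lengths(synsets$lemmas) == 0L)) {
    abort("every synset must carry at least one lemma")
  }

  if (is.null(edges) || nrow(as_tibble(edges)) == 0L) {
    edges <- tibble(hyponym = character(), hypernym = character())
  }
  edges <- as_tibble(edges)[, c("hyponym", "hypernym")]
  missing_ep <- setdiff(c(edges$hyponym, edges$hypernym), synsets$id)
  if (length(missing_ep)) {
    abort(paste0("edge references unknown synset: ", missing_ep[1]))
  }
  pos_of <- stats::setNames(synsets$pos, synsets$id)
  cross <- pos_of[edges$hyponym] != pos_of[edges$hypernym]
  if (any(cross)) {
    abort(paste0(
      "is-a edge crosses word classes: ",
      edges$hyponym[cross][1], " -> ", edges$hypernym[cross][1]
    ))
  }

  cyc <- find_cycle_member(synsets$id, edges)
  if (!is.na(cyc)) {
    abort(paste0("taxonomy contains a cycle through synset: ", cyc))
  }

  synsets$depth <- synset_depths_all(synsets, edges)

  lemma_index <- synsets %>%
    mutate(.ord = row_number()) %>%
    select("id", "pos", "lemmas", ".ord") %>%
    tidyr::unnest_longer("lemmas", values_to = "lemma") %>%
    arrange(.data$lemma, .data$pos, .data$.ord) %>%
    group_by(.data$lemma, .data$pos) %>%
    mutate(sense_rank = row_number()) %>%
    ungroup() %>%
    select(lemma = "lemma", pos = "pos", synset_id = "id", sense_rank = "sense_rank")

  roots <- synsets$id[!synsets$id %in% edges$hyponym]

  structure(
    list(
      synsets = synsets[, c("id", "pos", "lemmas", "gloss", "depth")],
      edges = edges,
      lemma_index = lemma_index,
      roots = roots,
      meta = meta
    ),
    class = "taxonomy"
  )
}

# Kahn elimination; returns NA when acyclic, else the id of one synset on a
# cycle (deterministically the lexicographically first survivor).
find_cycle_member <- function(ids, edges) {
  if (nrow(edges) == 0L) return(NA_character_)
  alive <- ids
  e <- edges
  repeat {
    # removable: no outgoing (hypernym-ward) edge left
    removable <- setdiff(alive, unique(e$hyponym))
    if (!length(removable)) break
    alive <- setdiff(alive, removable)
    e <- e[e$hypernym %in% alive, , drop = FALSE]
    if (nrow(e) == 0L) return(NA_character_)
  }
  if (!length(alive)) return(NA_character_)
  sort(alive)[1]
}

# Minimum hypernym-edge count from every synset to any root of its pos.
synset_depths_all <- function(synsets, edges) {
  depth <- stats::setNames(rep(NA_real_, nrow(synsets)), synsets$id)
  roots <- synsets$id[!synsets$id %in% edges$hyponym]
  depth[roots] <- 0
  if (nrow(edges)) {
    g <- igraph::graph_from_data_frame(
      edges[, c("hyponym", "hypernym")],
      directed = TRUE,
      vertices = data.frame(name = synsets$id)
    )
    d <- igraph::distances(g, v = synsets$id, to = roots, mode = "out")
    depth[synsets$id] <- apply(d, 1, min)
  }
  if (any(!is.finite(depth))) {
    abort(paste0(
      "synset cannot reach a root of its word class: ",
      names(depth)[!is.finite(depth)][1]
    ))
  }
  as.integer(depth[synsets$id])
}

#' @export
print.taxonomy <- function(x, ...) {
  cat(
    "<taxonomy> ", nrow(x$synsets), " synsets, ", nrow(x$edges),
    " is-a edges, ", length(x$roots), " root(s)\n",
    sep = ""
  )
  tab <- table(x$synsets$pos)
  cat("  per class:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  if (length(x$meta)) {
    cat("  meta:", paste(names(x$meta), unlist(x$meta), sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Tidy a taxonomy into its synset table
#' @param x A `taxonomy`.
#' @param ... Unused.
#' @return Tibble with one row per synset: id, pos, lemmas (|-joined), depth.
#' @method tidy taxonomy
#' @export
tidy.taxonomy <- function(x, ...) {
  x$synsets %>%
    mutate(lemmas = vapply(.data$lemmas, paste, "", collapse = "|")) %>%
    select("id", "pos", "lemmas", "depth")
}

#' One-row summary of a taxonomy
#' @inheritParams tidy.taxonomy
#' @return Tibble with synset/edge/root counts and the maximum depth.
#' @method glance taxonomy
#' @export
glance.taxonomy <- function(x, ...) {
  tibble(
    n_synsets = nrow(x$synsets),
    n_edges = nrow(x$edges),
    n_roots = length(x$roots),
    n_lemmas = n_distinct(x$lemma_index$lemma),
    max_depth = max(x$synsets$depth)
  )
}

#' Read a taxonomy from an edge-list file
#'
#' The dialect is UTF-8, tab-separated, with `#` comment lines. Two record
#' types: `S<TAB>id<TAB>pos<TAB>lemma1|lemma2...<TAB>gloss` (gloss optional)
#' declares a synset; `E<TAB>hyponym_id<TAB>hypernym_id` declares an is-a
#' edge. Sense rank of a lemma follows S-record order.
#'
#' @param path File path.
#' @return A validated [taxonomy()].
#' @export
read_taxonomy <- function(path) {
  if (!file.exists(path)) abort(paste0("taxonomy file not found: ", path))
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  parts <- strsplit(lines, "\t", fixed = TRUE)

  syn <- list()
  edg <- list()
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    where <- paste0(" (line ", lineno[i], ")")
    if (p[1] == "S") {
      if (length(p) < 4L || length(p) > 5L) {
        abort(paste0("S record needs 4-5 fields", where))
      }
      syn[[length(syn) + 1L]] <- tibble(
        id = p[2], pos = p[3], lemmas = p[4],
        gloss = if (length(p) == 5L) p[5] else NA_character_
      )
    } else if (p[1] == "E") {
      if (length(p) != 3L) abort(paste0("E record needs 3 fields", where))
      edg[[length(edg) + 1L]] <- tibble(hyponym = p[2], hypernym = p[3])
    } else {
      abort(paste0("unknown record type '", p[1], "'", where))
    }
  }
  if (!length(syn)) abort("taxonomy file declares no synsets")
  taxonomy(
    bind_rows(syn), if (length(edg)) bind_rows(edg),
    meta = list(source = basename(path))
  )
}

#' Write a taxonomy in the canonical edge-list dialect
#'
#' Emits S records sorted by synset id, then E records sorted by
#' (hyponym, hypernym); the output is bit-exact reproducible, so
#' `write_taxonomy()` then [read_taxonomy()] round-trips.
#'
#' @param tax A `taxonomy`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_taxonomy <- function(tax, path) {
  stopifnot(inherits(tax, "taxonomy"))
  s <- tax$synsets %>% arrange(.data$id)
  s_lines <- paste(
    "S", s$id, s$pos,
    vapply(s$lemmas, paste, "", collapse = "|"),
    if_else(is.na(s$gloss), "", s$gloss),
    sep = "\t"
  )
  s_lines <- sub("\t$", "", s_lines)  # drop empty trailing gloss field
  e <- tax$edges %>% arrange(.data$hyponym, .data$hypernym)
  e_lines <- if (nrow(e)) paste("E", e$hyponym, e$hypernym, sep = "\t") else character()
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(s_lines, e_lines), con, useBytes = TRUE)
  invisible(path)
}

#' Depth of a synset
#'
#' The minimum number of hypernym ("is-a") edges from the synset to any root
#' of its word class; a root has depth 0. When a synset has several hypernym
#' paths (a DAG), the shortest one counts.
#'
#' @param tax A `taxonomy`.
#' @param id Synset id(s).
#' @return Integer vector of depths.
#' @export
synset_depth <- function(tax, id) {
  stopifnot(inherits(tax, "taxonomy"))
  m <- match(id, tax$synsets$id)
  if (anyNA(m)) abort(paste0("unknown synset id: ", id[is.na(m)][1]))
  tax$synsets$depth[m]
}

#' Semantic Depth Index of words
#'
#' For each (lemma, pos) pair, resolves the lemma in the taxonomy's lemma
#' index and scores its depth: the number of nodes separating the word from
#' the root of its word class (root excluded, i.e. the hypernym-path edge
#' count). Shallow values mark generic terms ("thing" = 1), deep values
#' specific ones ("cat" = 10 on the usual noun hierarchy). Polysemy is
#' resolved by `policy`:
#' \describe{
#'   \item{first_sense}{depth of the sense-rank-1 synset (default).}
#'   \item{min_depth / max_depth}{extreme depth across the lemma's synsets.}
#'   \item{mean_depth}{average depth across senses (may be fractional).}
#' }
#' Absent lemmas yield `found = FALSE`, never an error.
#'
#' @param tax A `taxonomy`.
#' @param lemma Character vector of lemmas (case-folded for lookup).
#' @param pos Word class(es), recycled against `lemma`.
#' @param policy Sense policy, see above.
#' @return Tibble with columns lemma, pos, sdi, synset_used, policy_used,
#'   found. `synset_used` is NA under `mean_depth`.
#' @examples
#' tax <- read_taxonomy(system.file("extdata", "cat-hypernyms.tsv", package = "semdepth"))
#' sdi(tax, c("cat", "animal"), "noun")
#' @export
sdi <- function(tax, lemma, pos,
                policy = c("first_sense", "min_depth", "max_depth", "mean_depth")) {
  stopifnot(inherits(tax, "taxonomy"))
  policy <- match.arg(policy)
  q <- tibble(lemma = tolower(lemma), pos = pos) %>%
    mutate(.row = row_number())
  hits <- q %>%
    inner_join(tax$lemma_index, by = c("lemma", "pos")) %>%
    mutate(depth = synset_depth(tax, .data$synset_id))
  if (nrow(hits) == 0L) {
    return(q %>%
      mutate(
        sdi = NA_real_, synset_used = NA_character_,
        policy_used = policy, found = FALSE
      ) %>%
      select("lemma", "pos", "sdi", "synset_used", "policy_used", "found"))
  }
  res <- hits %>%
    group_by(.data$.row) %>%
    summarise(
      sdi = switch(policy,
        first_sense = .data$depth[which.min(.data$sense_rank)],
        min_depth = min(.data$depth),
        max_depth = max(.data$depth),
        mean_depth = mean(.data$depth)
      ),
      synset_used = switch(policy,
        first_sense = .data$synset_id[which.min(.data$sense_rank)],
        min_depth = .data$synset_id[which.min(.data$depth)],
        max_depth = .data$synset_id[which.max(.data$depth)],
        mean_depth = NA_character_
      ),
      .groups = "drop"
    )
  q %>%
    left_join(res, by = ".row") %>%
    mutate(
      policy_used = policy,
      found = !is.na(.data$sdi)
    ) %>%
    select("lemma", "pos", "sdi", "synset_used", "policy_used", "found")
}

#' Add SDI columns to a word table
#'
#' Data-frame-first companion to [sdi()]: joins `sdi`, `synset_used` and
#' `found` onto any table holding `lemma` and `pos` columns.
#'
#' @param words Data frame with columns `lemma`, `pos`.
#' @param tax A `taxonomy`.
#' @param policy Sense policy, see [sdi()].
#' @return `words` with `sdi`, `synset_used`, `policy_used`, `found` appended.
#' @export
add_sdi <- function(words, tax, policy = "first_sense") {
  words <- as_tibble(words)
  s <- sdi(tax, words$lemma, words$pos, policy = policy)
  dplyr::bind_cols(words, s[, c("sdi", "synset_used", "policy_used", "found")])
}

#' Taxonomy coverage of a word list
#'
#' QC summary of how many (lemma, pos) pairs resolve in the taxonomy.
#'
#' @param words Data frame with columns `lemma`, `pos`.
#' @param tax A `taxonomy`.
#' @return List with `by_pos` (per-class found/missing counts and coverage),
#'   `missing` (the unresolved pairs), and overall `coverage` (NA for an
#'   empty word list).
#' @export
coverage_report <- function(words, tax) {
  words <- as_tibble(words)
  if (nrow(words) == 0L) {
    return(list(
      by_pos = tibble(
        pos = character(), n = integer(), n_found = integer(),
        n_missing = integer(), coverage = double()
      ),
      missing = tibble(lemma = character(), pos = character()),
      coverage = NA_real_
    ))
  }
  scored <- add_sdi(words, tax)
  by_pos <- scored %>%
    group_by(.data$pos) %>%
    summarise(
      n = n(),
      n_found = sum(.data$found),
      n_missing = sum(!.data$found),
      coverage = mean(.data$found),
      .groups = "drop"
    )
  list(
    by_pos = by_pos,
    missing = scored %>% filter(!.data$found) %>% select("lemma", "pos"),
    coverage = mean(scored$found)
  )
}

#' Build a taxonomy from an installed WordNet-format database
#'
#' Optional adapter for WordNet-database-format directories (the `index.pos`
#' / `data.pos` file pair layout). Reads the noun and verb hypernym graphs
#' (`@` and `@i` pointers) and the sense order from the index files. The
#' package never requires a real database: edge-list files via
#' [read_taxonomy()] are the first-class input.
#'
#' @param dir Directory holding `index.noun`, `data.noun` (and optionally
#'   `index.verb`, `data.verb`).
#' @param pos Word classes to import.
#' @return A [taxonomy()] with the source recorded in `meta`.
#' @export
taxonomy_from_wordnet <- function(dir, pos = c("noun", "verb")) {
  pos <- match.arg(pos, several.ok = TRUE)
  if (!dir.exists(dir) || !file.exists(file.path(dir, "data.noun"))) {
    abort(paste0(
      "no WordNet-format database at '", dir, "'. ",
      "Supply an edge-list taxonomy file and use read_taxonomy() instead."
    ))
  }
  pos_char <- c(noun = "n", verb = "v")
  all_syn <- list()
  all_edg <- list()
  all_idx <- list()
  for (p in pos) {
    dpath <- file.path(dir, paste0("data.", p))
    ipath <- file.path(dir, paste0("index.", p))
    if (!file.exists(dpath)) next
    dl <- readLines(dpath, warn = FALSE)
    dl <- dl[!startsWith(dl, "  ")]  # license header lines
    for (ln in dl) {
      f <- strsplit(ln, " ", fixed = TRUE)[[1]]
      off <- f[1]
      w_cnt <- strtoi(f[4], 16L)
      words <- gsub("_", " ", f[4 + 2 * seq_len(w_cnt) - 1], fixed = TRUE)
      words <- sub("\\(.*\\)$", "", words)  # strip adjective markers
      i <- 4 + 2 * w_cnt + 1
      p_cnt <- as.integer(f[i])
      id <- paste0(pos_char[p], off)
      gloss <- sub("^.*\\| ?", "", ln)
      all_syn[[id]] <- tibble(id = id, pos = p, lemmas = list(tolower(words)), gloss = gloss)
      if (p_cnt > 0) {
        for (k in seq_len(p_cnt)) {
          j <- i + 4 * (k - 1)
          sym <- f[j + 1]
          if (sym %in% c("@", "@i")) {
            all_edg[[length(all_edg) + 1L]] <-
              tibble(hyponym = id, hypernym = paste0(pos_char[p], f[j + 2]))
          }
        }
      }
    }
    if (file.exists(ipath)) {
      il <- readLines(ipath, warn = FALSE)
      il <- il[!startsWith(il, "  ")]
      for (ln in il) {
        f <- strsplit(trimws(ln), " +")[[1]]
        lem <- tolower(gsub("_", " ", f[1], fixed = TRUE))
        n_syn <- as.integer(f[3])
        offs <- utils::tail(f, n_syn)
        all_idx[[length(all_idx) + 1L]] <- tibble(
          lemma = lem, pos = p,
          synset_id = paste0(pos_char[p], offs),
          sense_rank = seq_len(n_syn)
        )
      }
    }
  }
  tax <- taxonomy(
    bind_rows(all_syn),
    if (length(all_edg)) bind_rows(all_edg),
    meta = list(source = paste0("wordnet-format:", normalizePath(dir)))
  )
  if (length(all_idx)) {
    idx <- bind_rows(all_idx) %>% filter(.data$synset_id %in% tax$synsets$id)
    if (nrow(idx)) tax$lemma_index <- idx
  }
  tax
}
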