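#' Desikan atlas regions
#'
#' The 34 gyral-based cortical parcels of the Desikan atlas, with the lobe
#' assignment used to order regional result tables.
#'
#' @return Tibble: `region` (FreeSurfer aparc label), `lobe`, in canonical
#'   table order (each region appears once; both hemispheres carry the same
#'   labels).
#' @export
desikan_regions <- function() {
  p <- thickness_params()
  p %>%
    filter(.data$hemisphere == "left") %>%
    select("lobe", "region")
}

thickness_params <- function() {
  path <- system.file("extdata", "cohort-thickness-params.tsv", package = "semdepth")
  readr::read_tsv(path, comment = "#", show_col_types = FALSE, progress = FALSE)
}

#' Semantic-network regions of interest
#'
#' The a-priori set of 14 cortical regions (x 2 hemispheres = 28 ROIs)
#' associated with concept representation, against whose thickness the mean
#' Semantic Depth Index is correlated. Two entries of the conceptual list
#' have no single Desikan label and are mapped: the anterior temporal lobe
#' to `temporalpole`, and the inferior frontal gyrus to `parsopercularis`
#' (its opercular subdivision). The mapping is recorded in `listed_as`.
#'
#' @return Tibble with 28 rows: `region` (Desikan label), `hemisphere`
#'   (`"left"`/`"right"`), `listed_as` (the conceptual ROI name).
#' @export
semantic_network_rois <- function() {
  base <- tibble(
    region = c(
      "temporalpole", "superiortemporal", "middletemporal",
      "inferiortemporal", "fusiform", "parahippocampal", "entorhinal",
      "parsopercularis", "caudalmiddlefrontal", "superiorfrontal",
      "precuneus", "supramarginal", "posteriorcingulate",
      "rostralanteriorcingulate"
    ),
    listed_as = c(
      "anterior temporal lobe", "superior temporal gyrus",
      "middle temporal gyrus", "inferior temporal gyrus", "fusiform gyrus",
      "parahippocampal gyrus", "entorhinal cortex",
      "inferior frontal gyrus", "caudal middle frontal gyrus",
      "superior frontal gyrus", "precuneus", "supramarginal gyrus",
      "posterior cingulate gyrus", "rostral anterior cingulate gyrus"
    )
  )
  tidyr::crossing(base, hemisphere = c("left", "right")) %>%
    arrange(factor(.data$region, levels = base$region), .data$hemisphere) %>%
    select("region", "hemisphere", "listed_as")
}

hemi_codes <- c(lh = "left", rh = "right", left = "left", right = "right")

#' Read a cortical-thickness table
#'
#' Accepts either format:
#' \itemize{
#'   \item wide, FreeSurfer aparc-stats style: columns `subject`, `group`,
#'     then `<region>_<lh|rh>_thickness` per parcel;
#'   \item long: columns `subject`, `group`, `region`, `hemi` (or
#'     `hemisphere`), `thickness_mm` (or `thickness`).
#' }
#' Region names must be Desikan aparc labels; an unknown label is an error
#' naming the offending column. Values outside the physiological range
#' (0, 6) mm raise a QC warning.
#'
#' @param path File path (tab-separated, `#` comments allowed).
#' @return Tibble of class `thickness_tbl`: `subject`, `group`, `region`,
#'   `hemisphere` (`"left"`/`"right"`), `thickness` (mm).
#' @export
read_thickness <- function(path) {
  if (!file.exists(path)) abort(paste0("thickness table not found: ", path))
  d <- readr::read_tsv(path, comment = "#", show_col_types = FALSE, progress = FALSE)
  known <- desikan_regions()$region
  if (any(grepl("_thickness$", names(d)))) {
    vals <- grep("_thickness$", names(d), value = TRUE)
    parsed <- regmatches(vals, regexec("^(.*)_(lh|rh)_thickness$", vals))
    bad <- vals[!vapply(parsed, function(p) length(p) == 3L && p[2] %in% known, TRUE)]
    if (length(bad)) {
      abort(paste0("unknown atlas label in column: ", bad[1]))
    }
    out <- d %>%
      tidyr::pivot_longer(
        all_of(vals),
        names_to = c("region", "hemisphere"),
        names_pattern = "^(.*)_(lh|rh)_thickness$",
        values_to = "thickness"
      ) %>%
      mutate(hemisphere = unname(hemi_codes[.data$hemisphere]))
  } else {
    names(d)[names(d) == "hemi"] <- "hemisphere"
    names(d)[names(d) == "thickness_mm"] <- "thickness"
    need <- c("subject", "group", "region", "hemisphere", "thickness")
    if (!all(need %in% names(d))) {
      abort(paste0(
        "long thickness table needs columns: ", paste(need, collapse = ", ")
      ))
    }
    bad <- setdiff(unique(d$region), known)
    if (length(bad)) abort(paste0("unknown atlas label: ", bad[1]))
    if (any(!d$hemisphere %in% names(hemi_codes))) {
      abort("hemisphere must be lh/rh or left/right")
    }
    out <- d %>% mutate(hemisphere = unname(hemi_codes[.data$hemisphere]))
  }
  out <- out %>%
    select("subject", "group", "region", "hemisphere", "thickness") %>%
    mutate(thickness = as.numeric(.data$thickness))
  if (any(out$thickness <= 0 | out$thickness >= 6, na.rm = TRUE)) {
    warn("thickness values outside the physiological range (0, 6) mm")
  }
  class(out) <- c("thickness_tbl", class(out))
  out
}

#' Write a thickness table
#'
#' @param tt A `thickness_tbl`.
#' @param path Output path.
#' @param format `"long"` (default; `subject group region hemi
#'   thickness_mm`) or `"wide"` (aparc-stats style columns).
#' @return `path`, invisibly.
#' @export
write_thickness <- function(tt, path, format = c("long", "wide")) {
  format <- match.arg(format)
  tt <- as_tibble(tt)
  con <- file(path, open = "wb")
  on.exit(close(con))
  fmt_num <- function(x) formatC(x, digits = 15, format = "g")
  if (format == "long") {
    hemi <- c(left = "lh", right = "rh")[tt$hemisphere]
    writeLines(
      c(
        "subject\tgroup\tregion\themi\tthickness_mm",
        paste(tt$subject, tt$group, tt$region, hemi, fmt_num(tt$thickness), sep = "\t")
      ),
      con, useBytes = TRUE
    )
  } else {
    wide <- tt %>%
      mutate(col = paste0(
        .data$region, "_", c(left = "lh", right = "rh")[.data$hemisphere],
        "_thickness"
      )) %>%
      select("subject", "group", "col", "thickness") %>%
      tidyr::pivot_wider(names_from = "col", values_from = "thickness")
    vals <- setdiff(names(wide), c("subject", "group"))
    body <- apply(
      cbind(wide$subject, wide$group, sapply(wide[vals], fmt_num)),
      1, paste, collapse = "\t"
    )
    writeLines(c(paste(c("subject", "group", vals), collapse = "\t"), body),
      con,
      useBytes = TRUE
    )
  }
  invisible(path)
}

#' Region-wise group contrast of cortical thickness
#'
#' One Mann-Whitney U test per (region, hemisphere) between a clinical group
#' and controls, with Benjamini-Hochberg adjustment across the whole region
#' family (all 68 region-hemisphere parcels when the full atlas is present).
#' Output rows are ordered by lobe, region, hemisphere.
#'
#' @param tt A `thickness_tbl`.
#' @param clinical_group,control_group Group labels; each needs n >= 2.
#' @param q FDR level used for the `significant` flag.
#' @return Tibble of class `thickness_contrast_tbl`: lobe, region,
#'   hemisphere, group means/SDs, n per group, `u`, `p_raw`, `p_fdr`,
#'   `significant`.
#' @export
group_thickness_contrast <- function(tt, clinical_group, control_group = "HC",
                                     q = 0.05) {
  tt <- as_tibble(tt)
  for (g in c(clinical_group, control_group)) {
    if (sum(tt$group == g) == 0L) abort(paste0("group not present: ", g))
  }
  sub <- tt %>% filter(.data$group %in% c(clinical_group, control_group))
  res <- sub %>%
    group_by(.data$region, .data$hemisphere) %>%
    summarise(
      n_clinical = sum(.data$group == clinical_group),
      n_control = sum(.data$group == control_group),
      mean_clinical = mean(.data$thickness[.data$group == clinical_group]),
      sd_clinical = stats::sd(.data$thickness[.data$group == clinical_group]),
      mean_control = mean(.data$thickness[.data$group == control_group]),
      sd_control = stats::sd(.data$thickness[.data$group == control_group]),
      mw = list(mann_whitney_u(
        .data$thickness[.data$group == clinical_group],
        .data$thickness[.data$group == control_group]
      )),
      .groups = "drop"
    )
  if (any(res$n_clinical < 2 | res$n_control < 2)) {
    abort("each group needs at least 2 subjects per region")
  }
  lobes <- desikan_regions()
  out <- res %>%
    mutate(
      u = vapply(.data$mw, function(m) m$u_reported, 0),
      p_raw = vapply(.data$mw, function(m) m$p_two_sided, 0),
      p_fdr = bh_fdr(.data$p_raw),
      significant = .data$p_fdr < q
    ) %>%
    select(-"mw") %>%
    left_join(lobes, by = "region") %>%
    arrange(
      factor(.data$region, levels = lobes$region),
      factor(.data$hemisphere, levels = c("left", "right"))
    ) %>%
    select(
      "lobe", "region", "hemisphere", "n_clinical", "n_control",
      "mean_clinical", "sd_clinical", "mean_control", "sd_control",
      "u", "p_raw", "p_fdr", "significant"
    )
  class(out) <- c("thickness_contrast_tbl", class(out))
  out
}

#' Correlate mean SDI with semantic-network cortical thickness
#'
#' Pearson correlation between per-speaker mean Semantic Depth Index and
#' regional thickness, one test per ROI, over the pooled clinical sample,
#' with Benjamini-Hochberg adjustment within the ROI family (28 tests for
#' the default semantic network). Every profile's speaker must have
#' thickness values; a mismatch is an error naming the subjects.
#'
#' @param profiles Tibble from [feature_profiles()] (clinical speakers).
#' @param tt A `thickness_tbl`.
#' @param rois ROI table as from [semantic_network_rois()].
#' @param q FDR level for the `significant` flag.
#' @return Tibble of class `sdi_cor_tbl`, sorted by adjusted p: region,
#'   hemisphere, n, r, p_raw, p_fdr, significant.
#' @export
correlate_sdi_thickness <- function(profiles, tt,
                                    rois = semantic_network_rois(),
                                    q = 0.05) {
  profiles <- as_tibble(profiles)
  tt <- as_tibble(tt)
  if (nrow(profiles) < 4L) abort("need at least 4 speakers")
  missing_subj <- setdiff(profiles$speaker, unique(tt$subject))
  if (length(missing_subj)) {
    abort(paste0(
      "no thickness values for speaker(s): ",
      paste(missing_subj, collapse = ", ")
    ))
  }
  dat <- rois %>%
    inner_join(tt, by = c("region", "hemisphere"),
               relationship = "many-to-many") %>%
    inner_join(
      profiles %>% select("speaker", "mean_sdi"),
      by = c(subject = "speaker")
    )
  chk <- dat %>% count(.data$region, .data$hemisphere)
  if (nrow(chk) < nrow(rois) || any(chk$n < nrow(profiles))) {
    abort("thickness table is missing ROI values for some speakers")
  }
  out <- dat %>%
    group_by(.data$region, .data$hemisphere) %>%
    summarise(
      res = list(pearson_r(.data$mean_sdi, .data$thickness)),
      .groups = "drop"
    ) %>%
    tidyr::unnest("res") %>%
    mutate(
      p_fdr = bh_fdr(.data$p_raw),
      significant = .data$p_fdr < q
    ) %>%
    arrange(.data$p_fdr, dplyr::desc(abs(.data$r)), .data$region, .data$hemisphere) %>%
    select("region", "hemisphere", "n", "r", "p_raw", "p_fdr", "significant")
  class(out) <- c("sdi_cor_tbl", class(out))
  out
}

#' Correlation forest plot for SDI-thickness results
#'
#' @param object An `sdi_cor_tbl` from [correlate_sdi_thickness()].
#' @param ... Unused.
#' @return A ggplot object: r per ROI, FDR-significant entries highlighted.
#' @method autoplot sdi_cor_tbl
#' @export
autoplot.sdi_cor_tbl <- function(object, ...) {
  d <- as_tibble(object) %>%
    mutate(roi = paste(.data$region, substr(.data$hemisphere, 1, 1)))
  ggplot2::ggplot(
    d,
    ggplot2::aes(
      x = .data$r, y = stats::reorder(.data$roi, .data$r),
      colour = .data$significant
    )
  ) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40", `TRUE` = "firebrick")) +
    ggplot2::labs(
      x = "Pearson r (mean SDI vs thickness)", y = NULL,
      colour = "FDR significant"
    ) +
    ggplot2::theme_minimal()
}

#' Atrophy map plot for group contrasts
#'
#' @param object A `thickness_contrast_tbl` from
#'   [group_thickness_contrast()].
#' @param ... Unused.
#' @return A ggplot object: -log10 adjusted p per region and hemisphere.
#' @method autoplot thickness_contrast_tbl
#' @export
autoplot.thickness_contrast_tbl <- function(object, ...) {
  d <- as_tibble(object)
  ggplot2::ggplot(
    d,
    ggplot2::aes(
      x = -log10(.data$p_fdr),
      y = stats::reorder(.data$region, -.data$p_fdr),
      colour = .data$significant
    )
  ) +
    ggplot2::geom_point(size = 1.8) +
    ggplot2::facet_wrap(~hemisphere) +
    ggplot2::geom_vline(xintercept = -log10(0.05), linetype = 2) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40", `TRUE` = "firebrick")) +
    ggplot2::labs(x = "-log10 p (FDR)", y = NULL, colour = "FDR significant") +
    ggplot2::theme_minimal()
}
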