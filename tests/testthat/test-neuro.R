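test_that("the semantic-network ROI table is the documented 28-entry set", {
  rois <- semantic_network_rois()
  expect_equal(nrow(rois), 28L)
  expect_equal(dplyr::n_distinct(rois$region), 14L)
  expect_true(all(rois$region %in% desikan_regions()$region))
  expect_equal(
    rois$region[rois$listed_as == "anterior temporal lobe"],
    rep("temporalpole", 2)
  )
  expect_equal(nrow(desikan_regions()), 34L)
})

test_that("wide aparc-style thickness tables parse and validate labels", {
  regions <- desikan_regions()$region
  subj <- c("s1", "s2", "s3")
  set.seed(9)
  wide <- tibble::tibble(subject = subj, group = c("svPPA", "lvPPA", "HC"))
  for (r in regions) {
    wide[[paste0(r, "_lh_thickness")]] <- round(stats::runif(3, 1.5, 3.5), 2)
    wide[[paste0(r, "_rh_thickness")]] <- round(stats::runif(3, 1.5, 3.5), 2)
  }
  f <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(wide, f)
  tt <- read_thickness(f)
  expect_equal(nrow(tt), 3L * 68L)
  expect_setequal(unique(tt$hemisphere), c("left", "right"))
  # a single named column maps to (region, hemisphere)
  ent <- tt[tt$region == "entorhinal" & tt$hemisphere == "left" & tt$subject == "s1", ]
  expect_equal(ent$thickness, wide$entorhinal_lh_thickness[1])
  # misspelled label rejected by column name
  bad <- wide
  names(bad)[names(bad) == "entorhinal_lh_thickness"] <- "entorinal_lh_thickness"
  readr::write_tsv(bad, f)
  expect_error(read_thickness(f), "entorinal_lh_thickness")
})

test_that("long format round-trips through the writer", {
  co <- simulate_cohort(cohort_config(seed = 21, n_sv = 2, n_lv = 2, n_hc = 2))
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_thickness(co$thickness, f1)
  tt <- read_thickness(f1)
  expect_equal(as.data.frame(tt), as.data.frame(co$thickness))
  write_thickness(tt, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)), readBin(f2, "raw", file.size(f2)))
  # wide writer round-trips values too
  write_thickness(tt, f2, format = "wide")
  tt_w <- read_thickness(f2)
  expect_equal(
    dplyr::arrange(as.data.frame(tt_w), subject, region, hemisphere),
    dplyr::arrange(as.data.frame(tt), subject, region, hemisphere)
  )
})

test_that("group contrasts cover every parcel and flag clear separations", {
  co <- simulate_cohort(cohort_config(seed = 22, n_sv = 4, n_lv = 4, n_hc = 6))
  tt <- co$thickness
  ctr <- group_thickness_contrast(tt, "svPPA", "HC")
  expect_equal(nrow(ctr), 68L)
  expect_equal(dplyr::n_distinct(ctr$region), 34L)
  # complete separation in a region forces u = 0 there
  tt2 <- tt
  sel <- tt2$region == "entorhinal" & tt2$hemisphere == "left"
  tt2$thickness[sel & tt2$group == "svPPA"] <- 1.0
  tt2$thickness[sel & tt2$group == "HC"] <- 3.0 + seq_len(sum(sel & tt2$group == "HC")) / 100
  ctr2 <- group_thickness_contrast(tt2, "svPPA", "HC")
  expect_equal(ctr2$u[ctr2$region == "entorhinal" & ctr2$hemisphere == "left"], 0)
  expect_error(group_thickness_contrast(tt, "nfvPPA", "HC"), "not present")
})

test_that("identical group distributions give p near 1 region-wise", {
  pars <- semdepth:::thickness_params()
  set.seed(33)
  subjects <- tibble::tibble(
    subject = sprintf("x%02d", 1:20),
    group = rep(c("svPPA", "HC"), each = 10)
  )
  tt <- tidyr::crossing(subjects, pars[, c("region", "hemisphere")])
  tt$thickness <- stats::rnorm(nrow(tt), 2.5, 0.3)  # same law in both groups
  ctr <- group_thickness_contrast(tt, "svPPA", "HC")
  expect_gt(mean(ctr$p_raw), 0.35)   # uniform p-values on average
  expect_false(any(ctr$p_fdr < 0.05))
})

test_that("SDI-thickness correlation is exact on a noiseless linear plant", {
  co <- simulate_cohort(cohort_config(seed = 23, n_sv = 3, n_lv = 5))
  prof <- co$profiles
  tt <- co$thickness
  sel <- tt$subject %in% prof$speaker
  tt$thickness[sel] <- 0.1 * prof$mean_sdi[match(tt$subject[sel], prof$speaker)] + 2
  cors <- correlate_sdi_thickness(prof, tt)
  expect_equal(nrow(cors), 28L)
  expect_true(all(abs(cors$r - 1) < 1e-12))
  expect_equal(length(unique(cors$p_fdr)), 1L)
})

test_that("correlations are invariant to affine rescaling of thickness", {
  co <- simulate_cohort(cohort_config(seed = 24, n_sv = 3, n_lv = 5))
  cors <- correlate_sdi_thickness(co$profiles, co$thickness)
  tt2 <- dplyr::mutate(co$thickness, thickness = 10 * .data$thickness + 3)
  cors2 <- correlate_sdi_thickness(co$profiles, tt2)
  expect_equal(cors2$r, cors$r)
  expect_equal(cors2$p_fdr, cors$p_fdr)
})

test_that("speakers without thickness values are named in the error", {
  co <- simulate_cohort(cohort_config(seed = 25, n_sv = 3, n_lv = 5))
  tt <- dplyr::filter(co$thickness, .data$subject != "sv01")
  expect_error(
    correlate_sdi_thickness(co$profiles, tt),
    "sv01"
  )
})
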