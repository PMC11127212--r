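test_that("isotope similarity is the overlap of normalized patterns", {
  p <- isotope_pattern("C6H12O6", 3)
  expect_equal(isotope_similarity(p, p), 100)
  expect_equal(isotope_similarity(c(1, 0), c(0, 1)), 0)
  expect_equal(isotope_similarity(c(0.9, 0.1), c(0.8, 0.2)), 90.0)
  # shorter pattern is padded with zeros
  expect_equal(isotope_similarity(c(0.9, 0.1), c(0.9, 0.05, 0.05)), 95.0)
  expect_error(isotope_similarity(c(0.5, 0.2), c(0.9, 0.1)), "normalized")
})

test_that("MS/MS score is the intensity-weighted matched reference fraction", {
  ref <- tibble::tibble(mz = c(100.0, 200.0), intensity = c(60, 40))
  expect_equal(msms_score(ref, ref), 100)
  far <- tibble::tibble(mz = c(150.0, 300.0), intensity = c(50, 50))
  expect_equal(msms_score(far, ref), 0)
  only_first <- tibble::tibble(mz = 100.0005, intensity = 10)
  expect_equal(msms_score(only_first, ref), 60.0)
  # each observed peak is usable once: one observed peak cannot match both
  # reference peaks even when both are within tolerance
  close_ref <- tibble::tibble(mz = c(100.000, 100.001), intensity = c(50, 50))
  one_obs <- tibble::tibble(mz = 100.0005, intensity = 10)
  expect_equal(msms_score(one_obs, close_ref, fragment_ppm = 20), 50.0)
  expect_error(msms_score(ref, tibble::tibble(mz = numeric(),
                                              intensity = numeric())),
               "at least one peak")
})

test_that("the CCS filter passes on either the percent or absolute branch", {
  tol <- match_tolerances()
  expect_true(ccs_within_tolerance(delta_ccs(263, 258.2), tol))   # pct branch
  expect_true(ccs_within_tolerance(delta_ccs(123.9, 120), tol))   # abs branch
  expect_false(ccs_within_tolerance(delta_ccs(310, 300), tol))    # fails both
  expect_error(match_tolerances(ppm = -1), "positive")
})

test_that("composite score is the mean of clamped available subscores", {
  tol <- match_tolerances()
  perfect <- tibble::tibble(dppm = 0, drt = 0, delta_ccs_pct = 0,
                            isotope_similarity = 100, msms_score = 100)
  expect_equal(composite_score(perfect, tol), 100)
  two_dims <- tibble::tibble(dppm = NA_real_, drt = NA_real_,
                             delta_ccs_pct = NA_real_,
                             isotope_similarity = 90, msms_score = 70)
  expect_equal(composite_score(two_dims, tol), 80)
  mass_rt <- tibble::tibble(dppm = 10, drt = 0.15, delta_ccs_pct = NA_real_,
                            isotope_similarity = NA_real_,
                            msms_score = NA_real_)
  expect_equal(composite_score(mass_rt, tol), 50)
  none <- tibble::tibble(dppm = NA_real_, drt = NA_real_,
                         delta_ccs_pct = NA_real_,
                         isotope_similarity = NA_real_,
                         msms_score = NA_real_)
  expect_error(composite_score(none, tol), "no available subscores")
})

test_that("ranking is deterministic under ties and input permutations", {
  cands <- tibble::tibble(
    name = c("b", "a", "c"), composite = c(47, 64, 47),
    dppm = c(5, 1, 2)
  )
  ranked <- rank_candidates(cands)
  expect_equal(ranked$name, c("a", "c", "b"))
  expect_equal(ranked$rank, 1:3)
  set.seed(99)
  for (i in 1:20) {
    perm <- rank_candidates(cands[sample(3), ])
    expect_equal(perm$name, ranked$name)
  }
})

test_that("MSI levels follow the orthogonal-property rules", {
  base <- tibble::tibble(
    authentic_standard = TRUE, passed_mz = TRUE, passed_isotope = TRUE,
    passed_rt = TRUE, passed_msms = TRUE, passed_ccs = TRUE
  )
  expect_equal(assign_msi_level(base), 1L)
  # CCS alone as the second orthogonal property still gives level 1
  no_msms <- base
  no_msms$passed_msms <- NA
  expect_equal(assign_msi_level(no_msms), 1L)
  # fragment match without an authentic standard: level 2
  in_silico <- base
  in_silico$authentic_standard <- FALSE
  expect_equal(assign_msi_level(in_silico), 2L)
  # accurate mass + isotope only: level 3
  mz_iso <- tibble::tibble(
    authentic_standard = FALSE, passed_mz = TRUE, passed_isotope = TRUE,
    passed_rt = NA, passed_msms = NA, passed_ccs = NA
  )
  expect_equal(assign_msi_level(mz_iso), 3L)
  weak <- mz_iso
  weak$passed_isotope <- NA
  expect_equal(assign_msi_level(weak), 4L)
})

test_that("candidate generation equals the exhaustive filter oracle", {
  set.seed(2024)
  for (i in 1:200) {
    inst <- random_match_instance()
    got <- generate_candidates(inst$feature, inst$library,
                               dimensions = inst$dimensions)
    got_keys <- sort(paste(got$hmdb_id, got$adduct, sep = "|"))
    want_keys <- oracle_candidate_keys(inst$feature, inst$library,
                                       match_tolerances(), inst$dimensions)
    expect_equal(got_keys, want_keys, label = paste("instance", i))
  }
})

test_that("candidate generation handles degenerate inputs", {
  ex <- tryptophan_funnel_example()
  empty <- generate_candidates(ex$feature, ex$library[0, ])
  expect_equal(nrow(empty), 0)
  expect_error(generate_candidates(ex$feature, ex$library,
                                   dimensions = character()),
               "at least one")
  # requested-but-missing dimensions are skipped and flagged, not failed
  no_ccs <- ex$feature
  no_ccs$ccs <- NA_real_
  out <- generate_candidates(no_ccs, ex$library)
  expect_true("ccs" %in% attr(out, "dimensions_skipped"))
  expect_gt(nrow(out), 1)
})

test_that("the worked tryptophan funnel narrows 10 -> 10 -> 5 -> 1", {
  ex <- tryptophan_funnel_example()
  rep <- annotation_funnel(ex$feature, ex$library)
  expect_equal(rep$stages$n_candidates, c(10L, 10L, 5L, 1L))
  expect_equal(rep$top_candidate$name, "l-Tryptophan")
  expect_equal(rep$top_candidate$msi_level, 1L)
  expect_s3_class(tidy(rep), "tbl_df")
  expect_s3_class(autoplot(rep), "ggplot")
  # without CCS on the feature the last stage keeps the 5 MS/MS survivors
  no_ccs <- ex$feature
  no_ccs$ccs <- NA_real_
  rep2 <- annotation_funnel(no_ccs, ex$library)
  expect_equal(rep2$stages$n_candidates, c(10L, 10L, 5L, 5L))
  # a feature matching nothing stops at zero
  stranger <- ex$feature
  stranger$mz <- 600.0
  rep3 <- annotation_funnel(stranger, ex$library)
  expect_equal(rep3$stages$n_candidates, rep(0L, 4))
  expect_null(rep3$top_candidate)
  # degenerate tolerances: all stages equal the first
  loose <- match_tolerances(ppm = 1e6, rt = 1e6, ccs_pct = 1e6,
                            ccs_abs = 1e6, isotope_min = 1e-9,
                            fragment_ppm = 1e6, msms_min = 0)
  rep4 <- annotation_funnel(ex$feature, ex$library, loose)
  expect_true(all(rep4$stages$n_candidates ==
                    rep4$stages$n_candidates[1]))
})

test_that("funnel stage counts never increase as criteria accumulate", {
  set.seed(31)
  lib <- urine_reference_library()
  feats <- simulate_features(lib[sample(nrow(lib), 10), ], 1,
                             noise_model(seed = 31))
  for (i in seq_len(nrow(feats))) {
    rep <- annotation_funnel(feats[i, ], lib)
    expect_true(all(diff(rep$stages$n_candidates) <= 0))
  }
})

test_that("every library record retrieves itself with a perfect score", {
  lib <- urine_reference_library()
  feats <- simulate_features(lib, 1, noise_model(0, 0, 0, 0, 0, seed = 1))
  for (i in seq_len(nrow(feats))) {
    cands <- generate_candidates(feats[i, ], lib)
    self <- cands[cands$hmdb_id == feats$true_hmdb_id[i] &
                    cands$adduct == feats$true_adduct[i], ]
    expect_equal(nrow(self), 1)
    expect_equal(self$composite, 100, tolerance = 1e-9)
    expect_equal(self$msi_level, 1L)
    # rank 1, except among records that are observationally identical in all
    # four dimensions (the glucuronic acid water-loss ion is indistinguishable
    # from protonated ascorbic acid by construction of the two molecules)
    rec <- lib[lib$hmdb_id == feats$true_hmdb_id[i] &
                 lib$adduct == feats$true_adduct[i], ]
    dup <- sum(lib$mode == rec$mode & lib$mz == rec$mz &
                 lib$rt == rec$rt & lib$ccs == rec$ccs)
    expect_lte(self$rank, dup)
  }
})

test_that("widening any tolerance never shrinks the candidate set", {
  ex <- tryptophan_funnel_example()
  base_tol <- match_tolerances()
  n_base <- nrow(generate_candidates(ex$feature, ex$library, base_tol))
  wider <- list(
    match_tolerances(ppm = 40),
    match_tolerances(rt = 0.6),
    match_tolerances(ccs_pct = 4),
    match_tolerances(ccs_abs = 8),
    match_tolerances(isotope_min = 40),
    match_tolerances(fragment_ppm = 40),
    match_tolerances(msms_min = 1)
  )
  for (tol in wider) {
    expect_gte(nrow(generate_candidates(ex$feature, ex$library, tol)), n_base)
  }
})
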