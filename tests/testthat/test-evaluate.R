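test_that("inter-day %RSD uses the sample SD and flags the worst compound", {
  r <- interday_rsd(tibble::tibble(
    compound = rep(c("flat", "spread"), each = 3),
    ccs = c(100, 100, 100, 99, 100, 101)
  ))
  expect_equal(r$rsd_pct[r$compound == "flat"], 0)
  expect_equal(r$rsd_pct[r$compound == "spread"], 1.0)
  expect_equal(worst_rsd(r), 1.0)
  expect_error(interday_rsd(tibble::tibble(compound = "x", ccs = 100)),
               ">= 2 replicates")
  # scale invariance
  reps <- tibble::tibble(compound = rep(letters[1:4], each = 3),
                         ccs = stats::runif(12, 100, 200))
  r1 <- interday_rsd(reps)
  r2 <- interday_rsd(dplyr::mutate(reps, ccs = ccs * 7.3))
  expect_equal(r1$rsd_pct, r2$rsd_pct, tolerance = 1e-12)
})

test_that("replicates at instrument-level noise stay under 2% RSD", {
  set.seed(24)
  lib <- urine_reference_library()
  true_ccs <- lib$ccs[1:20]
  reps <- tibble::tibble(
    compound = rep(sprintf("c%02d", 1:20), each = 3),
    ccs = rep(true_ccs, each = 3) * (1 + stats::rnorm(60, 0, 0.005))
  )
  expect_lt(worst_rsd(interday_rsd(reps)), 2)
})

test_that("accuracy report scores shared ions with inclusive thresholds", {
  m <- tibble::tibble(ion = c("a", "b"), ccs = c(102, 100))
  r <- tibble::tibble(ion = c("a", "b"), ccs = c(100, 100))
  rep <- accuracy_vs_reference(m, r, source = "DTIMS literature")
  # a deviation of exactly 2.0% counts as within +/- 2%
  expect_equal(rep$fraction_within, 1.0)
  expect_equal(rep$max_abs_pct, 2.0)
  same <- accuracy_vs_reference(m, m)
  expect_equal(same$fraction_within, 1.0)
  expect_equal(same$max_abs_pct, 0)
  out <- accuracy_vs_reference(tibble::tibble(ion = "a", ccs = 103),
                               tibble::tibble(ion = "a", ccs = 100))
  expect_equal(out$fraction_within, 0)
  expect_equal(out$max_abs_pct, 3.0)
  # unmatched ions are listed, never scored
  extra <- accuracy_vs_reference(
    tibble::tibble(ion = c("a", "only_m"), ccs = c(100, 150)),
    tibble::tibble(ion = c("a", "only_r"), ccs = c(100, 160))
  )
  expect_equal(nrow(extra$per_ion), 1)
  expect_equal(extra$unmatched_measured, "only_m")
  expect_equal(extra$unmatched_reference, "only_r")
  expect_error(
    accuracy_vs_reference(tibble::tibble(ion = "x", ccs = 1),
                          tibble::tibble(ion = "y", ccs = 1)),
    "no shared ions"
  )
  expect_s3_class(glance(rep), "tbl_df")
})

test_that("matrix effect compares spiked urine against neat solvent", {
  neat <- tibble::tibble(compound = c("a", "b"), ccs = c(150, 120))
  expect_equal(matrix_effect_report(neat, neat)$max_abs_pct, 0)
  one <- matrix_effect_report(tibble::tibble(compound = "a", ccs = 150.0),
                              tibble::tibble(compound = "a", ccs = 151.0))
  expect_equal(one$max_abs_pct, 100 * 1 / 150, tolerance = 1e-9)
  set.seed(62)
  spike <- tibble::tibble(compound = sprintf("s%02d", 1:62),
                          ccs = stats::runif(62, 110, 260))
  in_matrix <- dplyr::mutate(spike,
                             ccs = ccs * (1 + stats::rnorm(62, 0, 0.01)))
  # 1% noise stays within a documented 3-sigma style bound
  expect_lt(matrix_effect_report(spike, in_matrix)$max_abs_pct, 4)
})

test_that("trendline fits recover exact power laws and flag degeneracy", {
  exact <- tibble::tibble(mz = c(100, 400, 900), ccs = c(110, 220, 330))
  fit <- fit_class_trendlines(exact, per_class = FALSE)
  expect_equal(fit$a, 11, tolerance = 1e-9)
  expect_equal(fit$b, 0.5, tolerance = 1e-9)
  expect_equal(fit$r2, 1, tolerance = 1e-12)
  expect_equal(fit$r2_space, "log-log")
  flat <- tibble::tibble(mz = c(100, 200, 300), ccs = c(150, 150, 150))
  dfit <- fit_class_trendlines(flat, per_class = FALSE)
  expect_true(dfit$zero_variance)
  expect_equal(dfit$b, 0)
  expect_equal(dfit$r2, 1)
  set.seed(5)
  noisy <- tibble::tibble(mz = seq(90, 900, length.out = 40))
  noisy$ccs <- 11 * noisy$mz^0.5 * exp(stats::rnorm(40, 0, 0.05))
  nfit <- fit_class_trendlines(noisy, per_class = FALSE)
  expect_lt(abs(nfit$b - 0.5), 0.1)
  # small classes are skipped with a notice, the rest are fitted
  ions <- tibble::tibble(
    mz = c(100, 400, 900, 150, 350, 700, 250),
    ccs = c(110, 220, 330, 130, 200, 280, 160),
    class_label = c(rep("benzenoids", 3), rep("lipids", 3), "other")
  )
  expect_message(fits <- fit_class_trendlines(ions), "skipping")
  expect_setequal(fits$class_label, c("all", "benzenoids", "lipids"))
  expect_s3_class(autoplot(fits), "ggplot")
})

test_that("adduct shifts report paired mean and SD with sign convention", {
  lib <- tibble::tibble(
    name = rep(c("a", "b", "c"), each = 2),
    hmdb_id = rep(c("H1", "H2", "H3"), each = 2),
    formula = "C6H12O6",
    monoisotopic_mass = monoisotopic_mass("C6H12O6"),
    superclass = "other",
    adduct = rep(c("[M+H]+", "[M+Na]+"), 3),
    mode = "positive",
    mz = rep(c(181.07, 203.05), 3),
    rt = 1,
    ccs = c(120, 124, 130, 136, 140, 148),
    spectrum = list(NULL), spectrum_source = NA_character_,
    authentic_standard = TRUE
  )
  s <- adduct_shift_stats(lib, "[M+Na]+", "[M+H]+")
  expect_equal(s$n_pairs, 3)
  expect_equal(s$mean_shift, 6)
  expect_equal(s$sd_shift, 2)
  # antisymmetry under pair swap
  swapped <- adduct_shift_stats(lib, "[M+H]+", "[M+Na]+")
  expect_equal(swapped$mean_shift, -6)
  # single pair: SD undefined
  one <- adduct_shift_stats(lib[1:2, ], "[M+Na]+", "[M+H]+")
  expect_true(is.na(one$sd_shift))
  # water-loss ion smaller than its protonated parent gives a negative shift
  wl <- lib[1:2, ]
  wl$adduct <- c("[M+H-H2O]+", "[M+H]+")
  wl$ccs <- c(120, 124)
  expect_equal(adduct_shift_stats(wl, "[M+H-H2O]+", "[M+H]+")$mean_shift, -4)
  expect_error(adduct_shift_stats(lib, "[M-H]-", "[M+Na-2H]-"), "no compound")
})
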