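test_that("feature tables round trip through CSV + MSP", {
  lib <- urine_reference_library()
  feats <- simulate_features(lib[50:60, ], 1, noise_model(0, 0, 0, 0, 0,
                                                          seed = 2))
  path <- file.path(tempdir(), "feats_rt.csv")
  write_features(feats, path)
  back <- read_features(path)
  expect_equal(back$feature_id, feats$feature_id)
  expect_equal(back$mz, feats$mz, tolerance = 1e-4)
  expect_equal(back$rt, feats$rt, tolerance = 1e-2)
  expect_equal(back$ccs, feats$ccs, tolerance = 1e-2)
  has_frag <- !vapply(feats$fragments, is.null, logical(1))
  expect_equal(!vapply(back$fragments, is.null, logical(1)), has_frag)
  expect_equal(lengths(back$isotopes), lengths(feats$isotopes))
})

test_that("key-value run configurations parse with comments and defaults", {
  path <- file.path(tempdir(), "run.conf")
  writeLines(c(
    "# annotation run",
    "library = lib.csv",
    "ppm = 15",
    "msms_min = 20  # stricter fragment rule"
  ), path)
  conf <- read_run_config(path)
  expect_equal(conf$library, "lib.csv")
  expect_equal(conf$ppm, 15)
  expect_equal(conf$msms_min, 20)
  writeLines("no equals sign here", path)
  expect_error(read_run_config(path), "malformed")
})

test_that("the workflow annotates the worked example end to end", {
  ex <- tryptophan_funnel_example()
  out_matches <- file.path(tempdir(), "matches.csv")
  out_funnel <- file.path(tempdir(), "funnel.json")
  res <- run_annotate_workflow(ex$feature, ex$library,
                               out_matches = out_matches,
                               out_funnel = out_funnel)
  expect_equal(res$matches$name[res$matches$rank == 1], "l-Tryptophan")
  expect_equal(res$funnels[["URINE-TRP"]]$stages$n_candidates,
               c(10L, 10L, 5L, 1L))
  expect_equal(res$summary$n_features, 1L)
  expect_equal(res$summary$msi_level, 1L)
  funnel_json <- jsonlite::read_json(out_funnel)
  expect_equal(unlist(funnel_json[["URINE-TRP"]]$stages, use.names = FALSE),
               c(10L, 10L, 5L, 1L))
  expect_true(file.exists(out_matches))
})

test_that("self-annotation of the urine library confirms every compound", {
  lib <- urine_reference_library()
  feats <- simulate_features(lib, 1, noise_model(0, 0, 0, 0, 0, seed = 4))
  res <- run_annotate_workflow(feats, lib)
  top <- res$matches[res$matches$rank == 1, ]
  expect_equal(nrow(top), nrow(lib))
  expect_true(all(top$msi_level == 1L))
  expect_equal(sort(unique(top$hmdb_id)), sort(unique(lib$hmdb_id)))
  # per-mode level-1 counts match the library's entry counts per record mode
  by_mode <- table(top$mode)
  expect_equal(unname(by_mode[["positive"]]), 23)
  expect_equal(unname(by_mode[["negative"]]), 44)
  # an empty feature table is a valid no-op
  empty <- run_annotate_workflow(feats[0, ], lib)
  expect_equal(nrow(empty$matches), 0)
})

test_that("drift-time features are converted through the calibration", {
  lib <- urine_reference_library()[1:5, ]
  cal <- tibble::tibble(
    mz = seq(100, 700, length.out = 8), charge = 1L,
    drift_time = seq(1.5, 9, length.out = 8)
  )
  cal$reference_ccs <- denormalize_ccs(
    400 * corrected_drift_time(cal$drift_time, cal$mz, 1.41)^0.55,
    cal$mz, 1L, 28.0134
  )
  model <- fit_ccs_calibration(cal, edc_coefficient = 1.41)
  feats <- simulate_features(lib, 1, noise_model(0, 0, 0, 0, 0, seed = 6))
  # replace CCS by the drift time that maps back to it under the model
  td <- (normalize_ccs(feats$ccs, feats$mz) / 400)^(1 / 0.55)
  feats_dt <- feats
  feats_dt$ccs <- NA_real_
  feats_dt$drift_time <- td + 1.41 * sqrt(feats$mz) / 1000
  expect_error(run_annotate_workflow(feats_dt, lib), "calibration")
  res <- run_annotate_workflow(feats_dt, lib, calibration = model)
  top <- res$matches[res$matches$rank == 1, ]
  expect_equal(nrow(top), 5)
  expect_true(all(abs(top$delta_ccs_pct) < 1e-6))
})

test_that("identical configuration reruns produce byte-identical outputs", {
  lib <- urine_reference_library()
  feats <- simulate_features(lib[1:12, ], 1, noise_model(seed = 8))
  paths <- file.path(tempdir(), c("m1.csv", "m2.csv", "f1.json", "f2.json"))
  run_annotate_workflow(feats, lib, out_matches = paths[1],
                        out_funnel = paths[3])
  run_annotate_workflow(feats, lib, out_matches = paths[2],
                        out_funnel = paths[4])
  expect_identical(readLines(paths[1]), readLines(paths[2]))
  expect_identical(readLines(paths[3]), readLines(paths[4]))
})
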