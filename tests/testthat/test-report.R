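test_that("printed-baselines run reproduces the published grids on disk", {
  out <- withr::local_tempdir()
  cfg <- run_config(mode = "printed-baselines", out_dir = out, seed = 1)
  res <- run_analysis(cfg)
  expect_setequal(names(res), c("pcsm", "crpc", "metastasis"))

  excess <- read.csv(file.path(out, "pcsm_excess.csv"), check.names = FALSE,
                     colClasses = "character")
  expect_equal(names(excess), c("horizon_years", "x_pct",
                                "x1.25", "x1.50", "x1.75", "x2.00"))
  expect_equal(excess$x_pct, c("0.14", "0.99", "2.17"))
  expect_equal(excess$x1.25, c("0.04", "0.25", "0.54"))
  expect_equal(excess$x2.00, c("0.14", "0.99", "2.17"))

  nnh_tab <- read.csv(file.path(out, "pcsm_nnh.csv"), check.names = FALSE,
                      colClasses = "character")
  expect_equal(nnh_tab$x1.25, c("2857", "404", "184"))
  expect_equal(nnh_tab$x1.50, c("1429", "202", "92"))
  expect_equal(nnh_tab$x2.00, c("714", "101", "46"))

  # scaled curve coordinates exist per endpoint and start at S(0) = 1
  curve <- read.csv(file.path(out, "metastasis_scaled_survival.csv"),
                    check.names = FALSE)
  expect_equal(curve$time[1], 0)
  expect_equal(curve$observed[1], 1)
  expect_true(all(curve$x2.00 <= curve$observed))
})

test_that("secondary endpoints use the text-pinned 15-year baselines", {
  res <- run_analysis(run_config(endpoints = c("crpc", "metastasis"),
                                 multipliers = 2,
                                 out_dir = withr::local_tempdir()))
  crpc15 <- res$crpc$grid[res$crpc$grid$horizon == 15, ]
  expect_equal(format_percent(crpc15$excess_risk), "3.35")
  met15 <- res$metastasis$grid[res$metastasis$grid$horizon == 15, ]
  expect_equal(format_percent(met15$excess_risk), "3.47")
})

test_that("full-pipeline runs are byte-identical under a fixed seed", {
  spec <- fir_cohort_spec(n_subjects = 300)
  dirs <- c(withr::local_tempdir(), withr::local_tempdir())
  for (d in dirs) {
    run_analysis(run_config(mode = "full-pipeline", endpoints = "pcsm",
                            cohort = spec, out_dir = d, seed = 77))
  }
  files <- list.files(dirs[1])
  expect_true(length(files) >= 5)  # cohort, 4 tables, log
  for (f in files) {
    expect_identical(readLines(file.path(dirs[1], f)),
                     readLines(file.path(dirs[2], f)))
  }
})

test_that("full-pipeline baselines come from the fitted curve", {
  spec <- fir_cohort_spec(n_subjects = 400)
  out <- withr::local_tempdir()
  res <- run_analysis(run_config(mode = "full-pipeline", endpoints = "pcsm",
                                 cohort = spec, out_dir = out, seed = 123))
  spec$seed <- 123L
  cohort <- generate_cohort(spec)
  fit <- km_fit(cohort$pcsm_time, cohort$pcsm_event)
  expect_equal(unname(res$pcsm$baselines),
               as.numeric(risk_at(fit, c(5, 10, 15))))
  expect_true(file.exists(file.path(out, "cohort.csv")))
})

test_that("empty multiplier list yields header-only grid tables", {
  out <- withr::local_tempdir()
  run_analysis(run_config(endpoints = "pcsm", multipliers = numeric(0),
                          out_dir = out))
  excess <- read.csv(file.path(out, "pcsm_excess.csv"))
  expect_equal(nrow(excess), 0)
  expect_equal(names(excess), c("horizon_years", "x_pct"))
})

test_that("YAML configuration round trips into an identical analysis", {
  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  cfg_path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "mode: printed-baselines",
    "endpoints: [pcsm]",
    "multipliers: [1.25, 2.0]",
    "baselines:",
    "  pcsm: {5: 0.0014, 10: 0.0099, 15: 0.0217}",
    paste0("out_dir: ", out1),
    "seed: 4"
  ), cfg_path)
  cfg <- read_run_config(cfg_path)
  expect_s3_class(cfg, "run_config")
  expect_equal(cfg$multipliers, c(1.25, 2))
  run_analysis(cfg)
  run_analysis(run_config(endpoints = "pcsm", multipliers = c(1.25, 2),
                          baselines = fir_baseline_risks()["pcsm"],
                          out_dir = out2, seed = 4))
  expect_identical(readLines(file.path(out1, "pcsm_excess.csv")),
                   readLines(file.path(out2, "pcsm_excess.csv")))
})

test_that("cohort specs serialize through plain config lists", {
  lst <- list(
    n_subjects = 25,
    endpoint_hazards = list(
      pcsm = list(landmark_survival = list(`5` = 0.999, `10` = 0.990, `15` = 0.978)),
      crpc = list(knots = c(0, 5), rates = c(0.001, 0.002))
    ),
    accrual_years = list(first = 1990, modal = 2010, last = 2015),
    study_end_year = 2017,
    dropout_rate = 0,
    seed = 42
  )
  spec <- cohort_spec_from_list(lst)
  expect_s3_class(spec, "cohort_spec")
  expect_equal(ph_survival(spec$endpoint_hazards$pcsm, 10), 0.990)
  expect_equal(spec$endpoint_hazards$crpc$rates, c(0.001, 0.002))
  cohort <- generate_cohort(spec)
  expect_equal(nrow(cohort), 25)
})

test_that("configuration validation surfaces the offending key", {
  expect_error(run_config(endpoints = character(0)), "non-empty")
  expect_error(run_config(mode = "full-pipeline"), "cohort")
  expect_error(run_config(endpoints = "bone_mets"), "bone_mets")
  expect_error(run_config(multipliers = 0.5), ">= 1")
  expect_error(read_run_config("/nonexistent/x.yaml"), "not found")
})
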