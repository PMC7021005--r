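test_that("the model grid is the offsets x widths product with one clinical entry", {
  cfg <- study_config()
  grid <- build_model_grid(cfg)
  expect_length(grid, length(cfg$offsets_mm) * length(cfg$widths_mm))
  clin <- clinical_model(cfg)
  hits <- vapply(grid, function(m)
    m$leaf_tip_offset_mm == clin$leaf_tip_offset_mm &&
      m$leaf_tip_width_mm == clin$leaf_tip_width_mm, logical(1))
  expect_equal(sum(hits), 1)
  single <- build_model_grid(study_config(offsets_mm = 0, widths_mm = 4.5,
                                          clinical_offset_mm = 0))
  expect_length(single, 1)
  expect_equal(anyDuplicated(vapply(grid, `[[`, character(1), "model_id")), 0)
})

test_that("study configuration validates the clinical model and offsets", {
  expect_error(study_config(offsets_mm = c(-1, 0, 1)), "clinical")
  expect_error(study_config(offsets_mm = c(-0.5, 0, 1)), "uniform")
  expect_error(study_config(widths_mm = c(2.5, 6)), "clinical")
})

test_that("beam models and plans round-trip through their text formats", {
  m <- beam_model(-1.5, 6, 0.004, tip_rule = "literal")
  f <- withr::local_tempfile(fileext = ".dcf")
  write_beam_model(m, f)
  expect_equal(read_beam_model(f), m)
  suite <- generate_plan_suite(2)
  p <- suite[[2]]
  fp <- withr::local_tempfile(fileext = ".csv")
  write_plan(p, fp)
  q <- read_plan(fp)
  expect_equal(q$total_mu, p$total_mu, tolerance = 1e-9)
  expect_length(q$beams, length(p$beams))
  expect_equal(q$beams[[3]]$segments[[2]]$aperture,
               p$beams[[3]]$segments[[2]]$aperture, tolerance = 1e-12)
  g <- small_grid(20, 4)
  dm <- dose_map(g, matrix(runif(g$nx * g$ny), g$nx, g$ny))
  fd <- withr::local_tempfile(fileext = ".csv")
  write_dose_map(dm, fd)
  rt <- read_dose_map(fd)
  expect_equal(rt$grid, dm$grid)
  expect_equal(rt$values, dm$values, tolerance = 1e-9)
})

# A reduced-but-complete configuration exercising every stage quickly.
micro_config <- function(out_dir = NULL, seed = 1L) {
  study_config(offsets_mm = c(-1, -0.5, 0), widths_mm = 4.5,
               n_replicates = 2, master_seed = seed, out_dir = out_dir,
               grid = grid_spec(c(-101.5, -101.5), 2, 102, 102),
               array = array_spec(spacing_mm = 20, extent_mm = 60),
               eval_spacing_mm = 2)
}

test_that("sensitivity table has exact-zero clinical rows and monotone sign structure", {
  cfg <- micro_config()
  suite <- generate_plan_suite(cfg$master_seed)[c(1, 6)]
  sens <- run_sensitivity(cfg, suite = suite)
  expect_equal(nrow(sens), 2 * 3 * 4)  # plans x models x ROIs
  clin_rows <- sens$pct_diff[sens$offset_mm == -0.5]
  expect_identical(clin_rows, rep(0, sum(sens$offset_mm == -0.5)))
  expect_true(all(sens$pct_diff[sens$offset_mm < -0.5] <= 0))
  expect_true(all(sens$pct_diff[sens$offset_mm > -0.5] >= 0))
  for (key in split(seq_len(nrow(sens)),
                    paste(sens$plan_id, sens$roi))) {
    s <- sens[key, ]
    expect_true(all(diff(s$pct_diff[order(s$offset_mm)]) >= -1e-9))
  }
})

test_that("detectability produces labeled records and coherent ROC summaries", {
  cfg <- micro_config()
  suite <- generate_plan_suite(cfg$master_seed)[c(2, 7)]
  det <- run_detectability(cfg, suite = suite)
  rec <- det$records
  # plans x candidates x criteria x replicates
  expect_equal(nrow(rec), 2 * 3 * 2 * 2)
  expect_true(all(rec$label[rec$offset_mm == -0.5] == "negative"))
  expect_true(all(rec$label[rec$offset_mm != -0.5] == "positive"))
  expect_true(all(rec$pass_rate >= 0 & rec$pass_rate <= 100))
  summ <- det$roc_summary
  # offsets -1 and 0 both deviate by 0.5 mm from the clinical -0.5, so
  # there is one magnitude row plus a pooled row, per criteria preset
  expect_equal(nrow(summ), (1 + 1) * 2)
  expect_true(all(summ$auc >= 0 & summ$auc <= 1))
  for (cv in det$curves) {
    expect_equal(cv$curve$tpr[1], 0)
    expect_equal(cv$curve$fpr[nrow(cv$curve)], 1)
    expect_true(all(diff(cv$curve$tpr) >= 0))
  }
})

test_that("zero-noise truth-model records pass at 100%", {
  cfg <- study_config(offsets_mm = c(-1, -0.5, 0), widths_mm = 4.5,
                      n_replicates = 1, noise_sigma_pct = 0,
                      grid = grid_spec(c(-101.5, -101.5), 2, 102, 102),
                      array = array_spec(spacing_mm = 20, extent_mm = 60,
                                         noise_sigma_pct = 0),
                      eval_spacing_mm = 2)
  suite <- generate_plan_suite(1)[c(3)]
  det <- run_detectability(cfg, suite = suite)
  neg <- det$records[det$records$label == "negative", ]
  expect_true(all(neg$pass_rate == 100))
})

test_that("a full micro study is deterministic and writes parseable outputs", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  r1 <- run_study(micro_config(out_dir = d1), verbose = FALSE)
  r2 <- run_study(micro_config(out_dir = d2), verbose = FALSE)
  files <- c("suite_manifest.csv", "sensitivity.csv",
             "sensitivity_summary.csv", "qa_records.csv", "roc_summary.csv")
  for (f in files) {
    expect_true(file.exists(file.path(d1, f)))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
    expect_silent(utils::read.csv(file.path(d1, f)))
  }
  man <- as.data.frame(read.dcf(file.path(d1, "manifest.dcf")))
  expect_equal(as.integer(as.character(man$master_seed)), 1L)
  expect_equal(as.integer(as.character(man$n_plans)), 9L)
  # the manifest records the seed of every plan
  expect_length(strsplit(as.character(man$plan_seeds), ";")[[1]], 9)
  # distinct master seeds give distinct results
  r3 <- run_study(micro_config(seed = 2), verbose = FALSE)
  expect_false(isTRUE(all.equal(r1$sensitivity$dose, r3$sensitivity$dose)))
})
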