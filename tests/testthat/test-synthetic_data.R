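test_that("simulate_positions honours counts, classes and the field", {
  cfg <- synth_config(n_cells = 0)
  expect_equal(nrow(simulate_positions(cfg, seed = 1)), 0)
  cfg0 <- synth_config(qcc_fraction = 0)
  expect_equal(sum(simulate_positions(cfg0, seed = 1)$is_qcc), 0)
  # csr realized QCC count within 3 binomial SE of the target
  cfg5 <- synth_config(n_cells = 10000, qcc_fraction = 0.05)
  pos <- simulate_positions(cfg5, seed = 2)
  se <- sqrt(10000 * 0.05 * 0.95)
  expect_lt(abs(sum(pos$is_qcc) - 500), 3 * se)
  expect_true(all(pos$x >= 0 & pos$x <= cfg5$field[["width"]]))
  expect_true(all(pos$y >= 0 & pos$y <= cfg5$field[["height"]]))
  # thomas: QCCs cluster around parents
  cfgT <- synth_config(n_cells = 2000, spatial_model = "thomas")
  posT <- simulate_positions(cfgT, seed = 3)
  expect_equal(sum(posT$is_qcc), round(0.05 * 2000))
  expect_true(all(!is.na(posT$parent[posT$is_qcc])))
})

test_that("generated sections pass validation and round-trip the CSV I/O", {
  cfg <- synth_config(n_cells = 300)
  sim <- simulate_section(cfg, seed = 10)
  expect_s3_class(sim$section, "section_table")  # constructor validated it
  expect_equal(nrow(sim$truth), nrow(sim$section$cells))
  d <- withr::local_tempdir()
  simulate_cohort(cfg, seeds = c(4, 5), outdir = d)
  f1 <- file.path(d, "S01_cells.csv")
  expect_true(file.exists(f1) && file.exists(file.path(d, "manifest.json")))
  back <- read_cell_table(f1, file.path(d, "S01_fovs.csv"))
  expect_equal(nrow(back$cells), nrow(simulate_section(cfg, 4)$section$cells))
  # byte-identical on rerun
  h1 <- tools::md5sum(f1)
  simulate_cohort(cfg, seeds = c(4, 5), outdir = d)
  expect_identical(tools::md5sum(f1), h1)
})

test_that("batch scaling changes absolute calls but not relative calls", {
  cfg1 <- synth_config(n_cells = 500)
  cfg3 <- synth_config(n_cells = 500,
                       batch_scale = c(AKT = 3, H3K9me2 = 0.4, HES1 = 7))
  s1 <- simulate_section(cfg1, seed = 6)$section
  s3 <- simulate_section(cfg3, seed = 6)$section  # identical draws, rescaled
  expect_equal(s3$cells$AKT_cytoplasm_mean, 3 * s1$cells$AKT_cytoplasm_mean)
  rel1 <- call_qcc(s1); rel3 <- call_qcc(s3)
  expect_identical(rel1$qcc_label, rel3$qcc_label)
  cuts <- attr(rel1, "thresholds")
  abs_cfg <- threshold_config(mode = "absolute", absolute_cutoffs = cuts)
  expect_false(identical(call_qcc(s1, abs_cfg)$qcc_label,
                         call_qcc(s3, abs_cfg)$qcc_label))
})

test_that("strong class separation yields high recall at t = 0.25", {
  recalls <- sapply(1:5, function(s) {
    sim <- simulate_section(synth_config(n_cells = 1000), seed = 100 + s)
    lab <- call_qcc(sim$section)
    truth <- sim$truth$is_qcc[match(lab$cell_id, sim$truth$cell_id)]
    sum(lab$qcc_label & truth) / sum(truth)
  })
  expect_true(all(recalls >= 0.9))
})

test_that("zero class separation recovers truth no better than chance", {
  sim <- simulate_section(null_intensity_config(n_cells = 4000,
                                                qcc_fraction = 0.05),
                          seed = 17)
  lab <- call_qcc(select_tumor_cells(sim$section))
  truth <- sim$truth$is_qcc[match(lab$cell_id, sim$truth$cell_id)]
  # called set is independent of truth: overlap ~ hypergeometric
  n <- length(truth); n_called <- sum(lab$qcc_label); n_true <- sum(truth)
  exp_overlap <- n_called * n_true / n
  se <- sqrt(exp_overlap)  # Poisson-scale bound on the overlap count
  expect_lt(abs(sum(lab$qcc_label & truth) - exp_overlap), 4 * se + 2)
})

test_that("tighter clusters raise the cluster index", {
  cis <- sapply(c(0.30, 0.02), function(fr) {
    cfg <- synth_config(n_cells = 800, spatial_model = "thomas",
                        sigma = fr * 4176)
    mean(sapply(1:3, function(s) {
      sim <- simulate_section(cfg, seed = 200 + s)
      map <- stitch(sim$section,
                    call_qcc(select_tumor_cells(sim$section)))
      qcc_ci(map, cluster_index_config(k = 20))$qcc_ci
    }))
  })
  expect_gt(cis[2], cis[1])
})

test_that("contiguous sections sharing parents have closer QCC-P/geometry", {
  cfg <- synth_config(n_cells = 600, spatial_model = "thomas")
  set.seed(33)
  parents <- cbind(runif(5, 0, cfg$field[["width"]]),
                   runif(5, 0, cfg$field[["height"]]))
  a <- simulate_section(cfg, seed = 41, parents = parents)
  b <- simulate_section(cfg, seed = 42, parents = parents)
  c_ <- simulate_section(cfg, seed = 43)  # independent parents
  # mean QCC position is parent-driven: contiguous pair agrees more closely
  centroid <- function(sim) {
    m <- stitch(sim$section)
    q <- sim$truth$is_qcc[match(m$cell_id, sim$truth$cell_id)]
    c(mean(m$x[q]), mean(m$y[q]))
  }
  d_ab <- sqrt(sum((centroid(a) - centroid(b))^2))
  d_ac <- sqrt(sum((centroid(a) - centroid(c_))^2))
  expect_lt(d_ab, d_ac)
})

test_that("two-group cohorts with distinct QCC fractions are detectable", {
  # scaled down from the 100-replicate / 10+16-section design for test budget
  hits <- sapply(1:10, function(r) {
    pre <- sapply(1:5, function(i) {
      sim <- simulate_section(synth_config(n_cells = 500, qcc_fraction = 0.02),
                              seed = 1000 * r + i)
      qcc_percentage(call_qcc(select_tumor_cells(sim$section)))
    })
    post <- sapply(1:8, function(i) {
      sim <- simulate_section(synth_config(n_cells = 500, qcc_fraction = 0.06),
                              seed = 1000 * r + 100 + i)
      qcc_percentage(call_qcc(select_tumor_cells(sim$section)))
    })
    group_compare(post, pre)$p_value < 0.05
  })
  expect_gte(mean(hits), 0.8)
})
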