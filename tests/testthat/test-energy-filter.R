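test_that("ddG tables parse, validate, and round-trip", {
  recs <- make_records(c("T1", "T1", "T2"), c("mA", "mB", "mA"),
                       c(0.8, 1.2, 0.31))
  recs$run_values <- I(list(c(0.7, 0.9), c(1.1, 1.3), c(0.31, 0.31)))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_ddg_table(recs, path)
  got <- read_ddg_table(path)
  expect_equal(nrow(got), 3)
  expect_equal(got$ddg, recs$ddg, tolerance = 1e-12)
  expect_equal(got$run_values[[1]], c(0.7, 0.9), tolerance = 1e-12)

  self <- make_records("T1", "mA", 0.5, wt = "L", mut = "L")
  write_ddg_table(self, path)
  expect_error(read_ddg_table(path), "self-mutation")

  bad <- make_records("T1", "mA", 0.5, mut = "B")
  write_ddg_table(bad, path)
  expect_error(read_ddg_table(path), "'B'")

  dup <- make_records(c("T1", "T1"), c("mA", "mA"), c(0.5, 0.6))
  write_ddg_table(dup, path)
  expect_error(read_ddg_table(path), "duplicate")

  off <- make_records("T1", "mA", 0.5)
  off$run_values <- I(list(c(0.1, 0.2)))
  write_ddg_table(off, path)
  expect_error(read_ddg_table(path), "mean of run_values")
})

test_that("run aggregation is mean plus sample sd", {
  expect_equal(aggregate_runs(rep(0.1, 10)), c(mean = 0.1, sd = 0))
  expect_equal(aggregate_runs(seq(0.1, 1.0, by = 0.1))[["mean"]], 0.55)
  expect_equal(aggregate_runs(0.7), c(mean = 0.7, sd = 0))
  expect_equal(aggregate_runs(c(1, 3))[["sd"]], stats::sd(c(1, 3)))
  expect_error(aggregate_runs(numeric(0)), "at least one")
})

test_that("the energy filter demands destabilization everywhere", {
  params <- energy_filter_params()
  full <- make_records(rep(c("T1", "T2"), each = 2),
                       rep(c("mA", "mB"), 2), c(0.8, 1.2, 0.3, 0.05))
  v <- energy_filter_position(full, c("DIP_1", "Dpr_2"), "Dpr", 1,
                              expected_templates = c("T1", "T2"),
                              expected_members = c("mA", "mB"),
                              params = params)
  expect_true(v$passed)            # 0.05 is inclusive: at the noise floor
  expect_equal(v$min_ddg, 0.05)
  expect_true(v$coverage_complete)

  below <- full; below$ddg[4] <- 0.04
  vb <- energy_filter_position(below, c("DIP_1", "Dpr_2"), "Dpr", 1,
                               c("T1", "T2"), c("mA", "mB"), params)
  expect_false(vb$passed)

  # fail-closed on missing coverage
  partial <- full[-3, ]
  vp <- energy_filter_position(partial, c("DIP_1", "Dpr_2"), "Dpr", 1,
                               c("T1", "T2"), c("mA", "mB"), params)
  expect_false(vp$coverage_complete)
  expect_false(vp$passed)

  # an exempt combination (member shares wild type) is not required
  ve <- energy_filter_position(partial, c("DIP_1", "Dpr_2"), "Dpr", 1,
                               c("T1", "T2"), c("mA", "mB"), params,
                               exempt = data.frame(template_id = "T2",
                                                   source_member = "mA"))
  expect_true(ve$passed)

  # all combinations exempt: not evaluable, never passed
  va <- energy_filter_position(full[0, ], c("DIP_1", "Dpr_2"), "Dpr", 1,
                               "T1", "mA", params,
                               exempt = data.frame(template_id = "T1",
                                                   source_member = "mA"))
  expect_equal(va$status, "not_applicable")
  expect_false(va$passed)

  expect_error(energy_filter_position(full, c("DIP_1", "Dpr_2"), "Dpr", 1,
                                      "T1", c("mA", "mB"), params),
               "unexpected template")
})

test_that("energy filter agrees exactly with explicit enumeration", {
  withr::local_seed(909)
  params <- energy_filter_params()
  for (i in 1:1000) {
    templates <- paste0("T", seq_len(sample(1:3, 1)))
    members <- paste0("m", seq_len(sample(1:3, 1)))
    grid <- expand.grid(template_id = templates, source_member = members,
                        stringsAsFactors = FALSE)
    exempt <- grid[stats::runif(nrow(grid)) < 0.2, , drop = FALSE]
    avail <- grid[!paste(grid$template_id, grid$source_member) %in%
                    paste(exempt$template_id, exempt$source_member), ,
                  drop = FALSE]
    present <- avail[stats::runif(nrow(avail)) < 0.85, , drop = FALSE]
    recs <- make_records(present$template_id, present$source_member,
                         round(stats::rnorm(nrow(present), 0.3, 0.4), 3))
    got <- energy_filter_position(recs, c("DIP_1", "Dpr_2"), "Dpr", 1,
                                  templates, members, params, exempt)
    want <- oracle_energy_filter(recs, templates, members, exempt,
                                 params$ddg_threshold)
    expect_identical(got$passed, want$passed)
    expect_identical(got$status, want$status)
  }
})

test_that("energy filter is monotone and order-invariant", {
  withr::local_seed(77)
  templates <- c("T1", "T2"); members <- c("mA", "mB", "mC")
  for (i in 1:100) {
    grid <- expand.grid(template_id = templates, source_member = members,
                        stringsAsFactors = FALSE)
    keep <- stats::runif(nrow(grid)) < 0.9
    recs <- make_records(grid$template_id[keep], grid$source_member[keep],
                         round(stats::rnorm(sum(keep), 0.2, 0.3), 3))
    thresholds <- sort(stats::runif(3, 0, 0.6))
    passes <- vapply(thresholds, function(th) {
      energy_filter_position(recs, c("DIP_1", "Dpr_2"), "Dpr", 1,
                             templates, members,
                             energy_filter_params(th))$passed
    }, logical(1))
    # raising the threshold never turns a fail into a pass
    expect_true(all(diff(passes) <= 0))
    if (nrow(recs) > 1) {
      perm <- recs[sample(nrow(recs)), ]
      expect_identical(
        energy_filter_position(perm, c("DIP_1", "Dpr_2"), "Dpr", 1,
                               templates, members)$passed,
        energy_filter_position(recs, c("DIP_1", "Dpr_2"), "Dpr", 1,
                               templates, members)$passed)
    }
  }
})

test_that("adding a record can only lower min_ddg and never rescue a fail", {
  withr::local_seed(55)
  templates <- "T1"; members <- c("mA", "mB")
  recs <- make_records("T1", c("mA", "mB"), c(0.4, 0.2))
  base <- energy_filter_position(recs, c("DIP_1", "Dpr_2"), "Dpr", 1,
                                 templates, members)
  expect_true(base$passed)
  # second mutation row for an already-covered member (different residue)
  extra <- make_records("T1", "mA", -0.1, mut = "P")
  more <- rbind(recs, extra)
  v2 <- energy_filter_position(more, c("DIP_1", "Dpr_2"), "Dpr", 1,
                               templates, members)
  expect_lte(v2$min_ddg, base$min_ddg)
  expect_false(v2$passed)   # complete coverage + one stabilizing row
})
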