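test_that("subgroup pair enumeration matches the closed form", {
  reg <- read_subgroup_registry(
    system.file("extdata", "dip_dpr_registry.txt", package = "negcon"))
  pairs <- enumerate_subgroup_pairs(reg)
  expect_equal(nrow(pairs$all_pairs), 49)
  expect_equal(nrow(pairs$cognate_pairs), 7)
  expect_equal(nrow(pairs$noncognate_pairs), 42)

  tiny <- subgroup_registry(list(d1 = "A"), list(p1 = "B"),
                            data.frame(dip_subgroup = "d1",
                                       dpr_subgroup = "p1"))
  tp <- enumerate_subgroup_pairs(tiny)
  expect_equal(nrow(tp$all_pairs), 1)
  expect_equal(nrow(tp$noncognate_pairs), 0)

  reg32 <- subgroup_registry(
    list(d1 = "A", d2 = "B", d3 = "C"), list(p1 = "D", p2 = "E"),
    data.frame(dip_subgroup = c("d1", "d2"), dpr_subgroup = c("p1", "p2")))
  expect_equal(nrow(enumerate_subgroup_pairs(reg32)$noncognate_pairs), 4)

  # fuzz: |noncognate| == |DIP| * |Dpr| - |cognate|
  withr::local_seed(21)
  for (i in 1:25) {
    nd <- sample(1:6, 1); np <- sample(1:6, 1); nc <- sample(0:min(nd, np), 1)
    cm <- data.frame(dip_subgroup = paste0("d", seq_len(nc)),
                     dpr_subgroup = paste0("p", sample(np, nc)))
    if (nc == 0) cm <- data.frame(dip_subgroup = "d1", dpr_subgroup = "p1")
    reg <- subgroup_registry(
      stats::setNames(as.list(paste0("D", seq_len(nd))), paste0("d", 1:nd)),
      stats::setNames(as.list(paste0("P", seq_len(np))), paste0("p", 1:np)),
      cm)
    got <- enumerate_subgroup_pairs(reg)
    expect_equal(nrow(got$noncognate_pairs),
                 nd * np - nrow(reg$cognate_map))
  }

  expect_error(subgroup_registry(
    list(d1 = "A"), list(p1 = "B"),
    data.frame(dip_subgroup = "dX", dpr_subgroup = "p1")), "unknown")
  expect_error(subgroup_registry(
    list(d1 = "A", d2 = "A"), list(p1 = "B"),
    data.frame(dip_subgroup = "d1", dpr_subgroup = "p1")),
    "more than one")
})

test_that("registry files round-trip", {
  reg <- read_subgroup_registry(
    system.file("extdata", "dip_dpr_registry.txt", package = "negcon"))
  path <- withr::local_tempfile(fileext = ".txt")
  write_subgroup_registry(reg, path)
  back <- read_subgroup_registry(path)
  expect_equal(back$dip_subgroups, reg$dip_subgroups)
  expect_equal(back$dpr_subgroups, reg$dpr_subgroups)
  expect_equal(back$cognate_map, reg$cognate_map)
  expect_equal(cognate_partner(reg, "DIP-alpha", "DIP"), "Dpr6/10")
  expect_equal(cognate_partner(reg, "Dpr11/15/16/17", "Dpr"), "DIP-gamma")
})

test_that("constraint calls are the intersection of the two filters", {
  ev <- function(pos, passed) data.frame(
    dip_subgroup = "d1", dpr_subgroup = "p2", side = "Dpr",
    family_position = pos, n_records = 4L, min_ddg = 0.5,
    coverage_complete = TRUE, passed = passed, status = "ok")
  vv <- function(pos, accepted) data.frame(
    dip_subgroup = "d1", dpr_subgroup = "p2", side = "Dpr",
    family_position = pos, subgroup_i = "p1", subgroup_j = "p2",
    entropy_i = 0.1, entropy_j = 0.1, identity_condition = accepted,
    property_percent = 0, size_percent = 0, accepted = accepted)

  energy <- do.call(rbind, lapply(c(7, 10, 29, 31), function(p) {
    ev(p, p %in% c(10, 29, 31))
  }))
  evo <- do.call(rbind, lapply(c(7, 10, 29, 31), function(p) {
    vv(p, p %in% c(7, 29, 31))
  }))
  calls <- call_negative_constraints(energy, evo)
  expect_equal(calls$family_position[calls$accepted], c(29, 31))
  expect_true(all(calls$family_position[calls$accepted] %in%
                    energy$family_position[energy$passed]))
  expect_true(all(calls$family_position[calls$accepted] %in%
                    evo$family_position[evo$accepted]))

  none <- call_negative_constraints(transform(energy, passed = FALSE), evo)
  expect_false(any(none$accepted))

  single <- call_negative_constraints(ev(5, TRUE), vv(5, TRUE))
  expect_true(single$accepted)

  # energy-passing key without an evolutionary verdict is an ordering error
  expect_error(call_negative_constraints(ev(5, TRUE), vv(6, TRUE)),
               "lacks an evolutionary verdict")
  # but an energy-failing key may lack one
  ok <- call_negative_constraints(ev(5, FALSE), vv(6, TRUE))
  expect_false(ok$accepted)
})

test_that("consensus voting honors the method threshold", {
  preds <- data.frame(
    method = c("GroupSim", "SDPpred", "SPEER", "GroupSim", "SDPpred",
               "GroupSim", "SDPpred", "SPEER", "MultiHarmony"),
    family_position = c(7, 7, 7, 12, 12, 29, 29, 29, 29))
  methods <- c("GroupSim", "SDPpred", "SPEER", "MultiHarmony")
  expect_equal(consensus_combiner(preds, methods, 3), c(7, 29))
  expect_equal(consensus_combiner(preds, methods, 4), 29)
  expect_equal(consensus_combiner(preds, methods, 1), c(7, 12, 29))
  # monotone decreasing in min_methods
  sets <- lapply(1:4, function(k) consensus_combiner(preds, methods, k))
  for (k in 2:4) expect_true(all(sets[[k]] %in% sets[[k - 1]]))
  expect_error(consensus_combiner(preds, methods, 5), "between 1 and")
  expect_error(consensus_combiner(
    data.frame(method = "Other", family_position = 1), methods, 3),
    "unlisted")
})

test_that("K_D ratios convert to binding free-energy changes", {
  expect_equal(kd_to_ddg(5, 5), 0)
  # the Dpr11 double mutant: 7.9 -> 131 uM at 25 C
  expect_equal(kd_to_ddg(7.9, 131), 1.9872e-3 * 298.15 * log(131 / 7.9),
               tolerance = 1e-12)
  expect_equal(kd_to_ddg(7.9, 131), 1.66, tolerance = 0.005)
  expect_equal(kd_to_ddg(10, 500), 2.32, tolerance = 0.005)
  expect_error(kd_to_ddg(0, 5), "positive")
  expect_error(kd_to_ddg(5, -1), "positive")

  withr::local_seed(4)
  for (i in 1:50) {
    a <- stats::runif(1, 0.1, 100); b <- stats::runif(1, 0.1, 100)
    c_ <- stats::runif(1, 0.1, 100)
    # antisymmetry and additivity over chained ratios
    expect_equal(kd_to_ddg(a, b), -kd_to_ddg(b, a), tolerance = 1e-12)
    expect_equal(kd_to_ddg(a, c_), kd_to_ddg(a, b) + kd_to_ddg(b, c_),
                 tolerance = 1e-12)
    # strictly increasing in the ratio
    expect_gt(kd_to_ddg(a, b * 1.01), kd_to_ddg(a, b))
  }
})

test_that("constraint reports are written sorted and reject duplicates", {
  calls <- data.frame(
    dip_subgroup = c("d2", "d1", "d1"), dpr_subgroup = "p2", side = "Dpr",
    family_position = c(3L, 9L, 2L), n_records = 4L, min_ddg = 0.4,
    coverage_complete = TRUE, status = "ok", energy_passed = TRUE,
    entropy_i = 0.1, entropy_j = 0.1, identity_condition = TRUE,
    property_percent = 100, size_percent = 0, evo_accepted = TRUE,
    accepted = TRUE)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_constraint_report(calls, path)
  got <- utils::read.delim(path)
  expect_equal(nrow(got), 3)
  expect_equal(got$family_position, c(2L, 9L, 3L))  # sorted by pair first

  write_constraint_report(calls[0, ], path)
  expect_equal(nrow(utils::read.delim(path)), 0)

  expect_error(write_constraint_report(rbind(calls, calls[1, ]), path),
               "duplicate")
})
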