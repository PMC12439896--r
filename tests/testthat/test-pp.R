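ppMemory <- function() {
  episodicMemory(c("crab", "shrimp", "predator"), 6, 12, 12)
}

test_that("what-query values are per-object sums, hide driven by danger", {
  mem <- ppMemory()
  vals <- ppActionValues(mem, 0, "what_when")
  expect_equal(vals, c(hunt_crab = 0, hunt_shrimp = 0, hide = 0,
                       roam = 0.5))
  p <- softmaxProbabilities(vals, 1)
  expect_equal(unname(p), c(1, 1, 1, exp(0.5)) / (3 + exp(0.5)),
               tolerance = 1e-12)
  expect_equal(unname(p[4]), 0.35466124439244340, tolerance = 1e-12)
  expect_equal(unname(p[1]), 0.21511291853585221, tolerance = 1e-12)

  # predator entries summing to -8 make hide worth 8 and near-certain
  mem2 <- mem
  mem2@values["predator", 3, c(5, 17)] <- c(-3, -5)
  vals2 <- ppActionValues(mem2, 2, "what_when")
  expect_equal(unname(vals2["hide"]), 8)
  expect_gt(softmaxProbabilities(vals2, 1)["hide"], 0.99)

  expect_equal(unname(softmaxProbabilities(vals2, 0)), rep(0.25, 4))
})

test_that("where-query values sum each region over objects and cells", {
  mem <- ppMemory()
  vals <- ppActionValues(mem, 0, "when_where")
  expect_length(vals, 10L)
  expect_equal(unname(vals), c(rep(0, 9), 0.5))
  p <- softmaxProbabilities(vals, 1)
  expect_equal(unname(p[10]), exp(0.5) / (9 + exp(0.5)), tolerance = 1e-12)
  expect_equal(unname(p[10]), 0.15482809896025465, tolerance = 1e-12)

  # crab mass in region 8 makes it the modal region
  mem2 <- mem
  mem2@values["crab", 1, regionCells(8)[1:4]] <- 0.25
  p2 <- softmaxProbabilities(ppActionValues(mem2, 0, "when_where"), 1)
  expect_identical(which.max(p2[1:9]), c(go_region_8 = 9L))

  # a region holding -8 of predator memory is the least likely choice
  mem3 <- mem2
  mem3@values["predator", 1, regionCells(3)[1:2]] <- c(-6, -2)
  p3 <- softmaxProbabilities(ppActionValues(mem3, 0, "when_where"), 1)
  expect_identical(unname(which.min(p3)), 4L)   # go_region_3
})

test_that("no predator is scheduled at hour 0, so hunts are never fatal", {
  cfg <- ppConfig("what_when")
  M <- memValues(ppMemory())
  set.seed(41)
  for (k in 1:20) {
    pl <- placeForHour(ppSchedule(cfg), 0, 12, 12)
    res <- cuttlemem:::.ppHour(M, 0, cfg, 1L, pl)  # hunt crab
    expect_true(res$outcome %in% c("ate_crab", "none"))
  }
})

test_that("a hiding agent is never caught, even with the predator adjacent", {
  cfg <- ppConfig("what_when")
  M <- memValues(ppMemory())
  set.seed(42)
  for (k in 1:50) {
    pl <- list(crab = c(9L, 9L), shrimp = c(1L, 9L), predator = c(5L, 1L))
    res <- cuttlemem:::.ppHour(M, 2, cfg, 3L, pl)  # hide
    expect_identical(res$outcome, "none")
    expect_identical(res$M, M)                     # no updates while hidden
  }
})

test_that("being caught writes one penalty update at the predator's cell", {
  cfg <- ppConfig("what_when")
  M <- memValues(ppMemory())
  set.seed(43)
  caught <- 0L
  for (k in 1:20) {
    pl <- list(crab = c(9L, 9L), predator = c(4L, 0L))  # 2 cells from start
    res <- cuttlemem:::.ppHour(M, 1, cfg, 4L, pl)       # roam, uncamouflaged
    if (res$outcome == "caught") {
      caught <- caught + 1L
      diff <- which(res$M != M, arr.ind = TRUE)
      expect_identical(nrow(diff), 1L)
      expect_identical(unname(diff[1, 1]), 3L)          # predator plane
      expect_identical(unname(diff[1, 2]), 2L)          # hour 1
      expect_equal(res$M[diff], 0.1 * (-8), tolerance = 1e-15)
    }
  }
  expect_gt(caught, 10L)  # pursuit from distance 2 nearly always succeeds
})

test_that("hunting a region where the target is absent extinguishes once", {
  cfg <- ppConfig("what_when")
  M <- memValues(ppMemory())
  # remembered shrimp mass in region 6 at hour 1, but shrimp start at hour 2
  center <- regionCenter(6)
  iC <- cellIndex(center[1], center[2], 12)
  M[2, 2, iC] <- 2.0
  set.seed(44)
  pl <- placeForHour(ppSchedule(cfg), 1, 12, 12)  # crab + predator only
  pl$predator <- c(11L, 0L)  # park the predator far from the agent's path
  res <- cuttlemem:::.ppHour(M, 1, cfg, 2L, pl)   # hunt shrimp
  expect_equal(unname(res$M[2, 2, iC]), 2.0 * 0.9, tolerance = 1e-15)
})

test_that("full runs have 1200 records and are deterministic", {
  cfg <- ppConfig("what_when", runs = 1)
  res <- runPp(cfg, seed = 9)
  expect_identical(nrow(res$records), 1200L)  # 200 days x 6 hours
  expect_true(all(res$records$outcome %in%
                    c("ate_crab", "ate_shrimp", "caught", "none")))
  expect_true(all(res$records$end_region %in% 0:8))
  cfg2 <- toyPpConfig("when_where")
  a <- runPp(cfg2, seed = 10)
  b <- runPp(cfg2, seed = 10)
  expect_identical(a$records, b$records)
  expect_identical(lapply(a$memories, memValues),
                   lapply(b$memories, memValues))
})

test_that("record and memory invariants hold over seeded toy batches", {
  for (mode in c("what_when", "when_where")) {
    res <- runPp(toyPpConfig(mode, runs = 4), seed = 13)
    rec <- res$records
    # at most one of ate_crab / ate_shrimp / caught per hour is structural:
    # outcome is a single field; verify its values and the hide guarantee
    expect_true(all(rec$outcome %in%
                      c("ate_crab", "ate_shrimp", "caught", "none")))
    expect_true(all(rec$outcome[rec$action == "hide"] == "none"))
    # predator never present outside hours 1-3
    expect_true(all(rec$hour[rec$outcome == "caught"] %in% 1:3))
    # shrimp only eaten during its scheduled hours
    expect_true(all(rec$hour[rec$outcome == "ate_shrimp"] %in% 2:5))
    for (mem in res$memories) {
      v <- memValues(mem)
      expect_true(all(v["predator", , ] <= 0))
      expect_true(all(v["crab", , ] >= 0 & v["crab", , ] <= 1))
      expect_true(all(v["shrimp", , ] >= 0 & v["shrimp", , ] <= 4))
    }
  }
})
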