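test_that("ladder calibration is an exact two-point fit and recovers collinear points", {
  cal <- calibrateLadder(data.frame(mobility = c(0.2, 0.8),
                                    mw_kda = c(100, 10)))
  expect_equal(mwOf(cal, 0.5), 10^1.5, tolerance = 1e-12)
  expect_equal(mwOf(cal, 0.2), 100, tolerance = 1e-9)
  expect_equal(mwOf(cal, 0.8), 10, tolerance = 1e-9)

  ## five collinear log-points: fit recovers slope/intercept, residuals 0
  slope <- -2.1; intercept <- 2.4
  mob <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  pts <- data.frame(mobility = mob, mw_kda = 10^(intercept + slope * mob))
  cal2 <- calibrateLadder(pts)
  expect_equal(cal2@slope, slope, tolerance = 1e-9)
  expect_equal(cal2@intercept, intercept, tolerance = 1e-9)
  expect_equal(mwOf(cal2, mob), pts$mw_kda, tolerance = 1e-9)

  expect_error(calibrateLadder(data.frame(mobility = c(0.2, 0.2),
                                          mw_kda = c(10, 20))),
               class = "habid_validation_error")
  expect_error(calibrateLadder(data.frame(mobility = c(0.2, 0.8),
                                          mw_kda = c(10, 100))),
               class = "habid_validation_error")  # positive slope
})

test_that("band matching merges within tolerance and splits same-lane clusters", {
  near <- bandTable(lane_id = c("L1", "L2"), mw_kda = c(50, 50.4),
                    intensity_pct = 1)
  bm <- matchBands(near, relTolerance = 0.02)
  expect_equal(nrow(presenceMatrix(bm)), 1L)
  expect_equal(unname(bandClasses(bm)), "monomorphic")

  far <- bandTable(lane_id = c("L1", "L2"), mw_kda = c(50, 60),
                   intensity_pct = 1)
  bm2 <- matchBands(far, relTolerance = 0.02)
  expect_equal(nrow(presenceMatrix(bm2)), 2L)
  expect_equal(sort(unname(bandClasses(bm2))), c("unique", "unique"))
  ## rows sorted by descending consensus MW
  expect_equal(consensusMW(bm2), c(60, 50))

  ## a chain linking two bands of one lane is split at the largest gap
  chain <- bandTable(lane_id = c("L1", "L2", "L1"),
                     mw_kda = c(50, 50.5, 51), intensity_pct = 1)
  bm3 <- matchBands(chain, relTolerance = 0.02)
  p <- presenceMatrix(bm3)
  expect_equal(nrow(p), 2L)
  expect_true(all(rowSums(p) >= 1))
  expect_false(any(apply(p, 1, function(r) r["L1"] > 1)))

  expect_error(matchBands(near[near$lane_id == "L1", ]),
               class = "habid_validation_error")
  noCoord <- data.frame(lane_id = c("L1", "L2"), band_id = c("a", "b"),
                        mobility = c(0.4, NA), mw_kda = c(NA, 30),
                        intensity_pct = 1)
  expect_error(matchBands(noCoord), class = "habid_validation_error")
})

test_that("band matching equals the brute-force transitive-closure oracle", {
  withr::with_seed(99, {
    for (rep in 1:100) {
      nlanes <- sample(3:6, 1)
      bands <- do.call(rbind, lapply(seq_len(nlanes), function(l)
        data.frame(lane_id = sprintf("L%d", l),
                   mw_kda = round(runif(sample(3:10, 1), 9, 120), 3),
                   intensity_pct = 1)))
      bt <- bandTable(lane_id = bands$lane_id, mw_kda = bands$mw_kda,
                      intensity_pct = bands$intensity_pct)
      bm <- matchBands(bt, relTolerance = 0.02)
      expect_identical(bandMatrixClusters(bm),
                       oracleBandClusters(bt, 0.02))
    }
  })
})

test_that("band classes follow presence counts", {
  p <- bandTable(lane_id = c("L1", "L2", "L3", "L4",   # all four: monomorphic
                             "L1",                     # one lane: unique
                             "L1", "L2"),              # two lanes: polymorphic
                 mw_kda = c(100, 100, 100, 100, 50, 20, 20),
                 intensity_pct = 1)
  bm <- matchBands(p, relTolerance = 0.02)
  cls <- setNames(bandClasses(bm), round(consensusMW(bm)))
  expect_equal(cls[["100"]], "monomorphic")
  expect_equal(cls[["50"]], "unique")
  expect_equal(cls[["20"]], "polymorphic")
})

test_that("polymorphism percentages truncate like the published tables", {
  expect_equal(displayPct(7 * 100 / 10), 70.00)
  expect_equal(displayPct(8 * 100 / 11), 72.72)   # truncation of 72.7272...
  expect_equal(displayPct(10 * 100 / 13), 76.92)
  expect_equal(displayPct(11 * 100 / 14), 78.57)
  expect_equal(displayPct(100 / 3, 1), 33.3)
})

test_that("report identities hold and lane order does not change any number", {
  fx <- makeStudyFixture()
  tol <- attr(fx$protein, "tolerance")
  rep1 <- polymorphismStats(matchBands(fx$protein, relTolerance = tol))
  tot <- reportTotals(rep1)
  expect_equal(tot[["monomorphic"]] + tot[["polymorphic"]], tot[["total"]])
  pl <- perLane(rep1)
  expect_equal(pl$monomorphic + pl$polymorphic, pl$total)

  ## permute lanes: same numbers per lane
  perm <- fx$protein[order(fx$protein$lane_id, decreasing = TRUE), ]
  rep2 <- polymorphismStats(matchBands(perm, relTolerance = tol))
  pl2 <- perLane(rep2)
  expect_equal(pl2[order(pl2$lane), -1], pl[order(pl$lane), -1],
               ignore_attr = TRUE)

  ## identical lanes give zero polymorphism everywhere
  same <- bandTable(lane_id = rep(c("A", "B", "C"), each = 3),
                    mw_kda = rep(c(90, 45, 20), 3), intensity_pct = 1)
  rep3 <- polymorphismStats(matchBands(same))
  expect_true(all(perLane(rep3)$pctPolymorphism == 0))
  expect_true(all(bandClasses(matchBands(same)) == "monomorphic"))
})

test_that("a lane with no usable bands reports a missing percentage, not zero", {
  ## zymogram path: lane L3 has a band outside every zone
  zones <- data.frame(locus = c("z1", "z2"), mobility_min = c(0.1, 0.5),
                      mobility_max = c(0.3, 0.7))
  bands <- bandTable(lane_id = c("L1", "L1", "L2", "L2", "L3"),
                     mobility = c(0.2, 0.6, 0.2, 0.6, 0.9),
                     intensity_pct = 1)
  expect_warning(repz <- zymogramStats(bands, zones), "outside all zones")
  pl <- perLane(repz)
  expect_true(is.na(pl$pctPolymorphism[pl$lane == "L3"]))
  expect_equal(pl$total[pl$lane == "L3"], 0)
})

test_that("zymogram counting is per locus, with multi-band zones collapsing", {
  fx <- makeStudyFixture()
  repz <- zymogramStats(fx$zymogram, fx$zones)
  pl <- perLane(repz)
  ## lane 1: two active loci, no polymorphism; double-banded zone 2 is one
  ## locus
  expect_equal(pl$total[pl$lane == "Euk-EH1"], 2L)
  expect_equal(pl$pctPolymorphism[pl$lane == "Euk-EH1"], 0)
  for (l in c("Euk-EH2", "Euk-EH3", "Euk-EH4")) {
    expect_equal(pl$total[pl$lane == l], 3L)
    expect_equal(displayPct(pl$pctPolymorphism[pl$lane == l], 1), 33.3)
  }
  expect_equal(unname(reportTotals(repz)),
               c(8, 3, 0, 11))  # monomorphic, polymorphic, unique, total
})

test_that("intensity summary matches a hand-computed normalization", {
  ## single lane, equal intensities: each band 25% of the gel, mean 25
  one <- bandTable(lane_id = rep("L1", 4), mw_kda = c(90, 60, 30, 10),
                   intensity_pct = rep(7, 4))
  s1 <- intensitySummary(one)
  expect_equal(s1$mean_intensity_pct, 25)

  ## one lane carries all signal
  two <- bandTable(lane_id = c("L1", "L1", "L2"), mw_kda = c(90, 60, 30),
                   intensity_pct = c(40, 60, 0))
  s2 <- intensitySummary(two)
  expect_equal(s2$mean_intensity_pct[s2$lane == "L2"], 0)
  expect_equal(s2$mean_intensity_pct[s2$lane == "L1"], 50)

  ## random four-lane gel against an independent spreadsheet-style
  ## recomputation
  gel <- withr::with_seed(7, bandTable(
    lane_id = rep(sprintf("L%d", 1:4), times = c(3, 5, 4, 2)),
    mw_kda = runif(14, 9, 120), intensity_pct = runif(14, 1, 20)))
  s3 <- intensitySummary(gel)
  norm <- gel$intensity_pct / sum(gel$intensity_pct) * 100
  byLane <- tapply(norm, gel$lane_id, mean)
  expect_equal(s3$mean_intensity_pct, as.vector(byLane[s3$lane]))

  zero <- bandTable(lane_id = c("L1", "L2"), mw_kda = c(50, 40),
                    intensity_pct = 0)
  expect_error(intensitySummary(zero), class = "habid_validation_error")
})

test_that("band tables and reports round-trip through CSV", {
  fx <- makeStudyFixture()
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeBandTable(fx$protein, tmp, header = c("fixture", "tolerance: 0.015"))
  back <- readBandTable(tmp)
  expect_equal(back$lane_id, fx$protein$lane_id)
  expect_equal(back$mw_kda, fx$protein$mw_kda)

  rep <- polymorphismStats(matchBands(fx$protein, relTolerance = 0.015))
  tmp2 <- withr::local_tempfile(fileext = ".csv")
  writePolymorphismReport(rep, tmp2)
  tab <- read.csv(tmp2)
  expect_equal(tab$pct_polymorphism[1:4], c(70.00, 76.92, 72.72, 78.57))
  expect_equal(tab$pct_polymorphism[6], 74.55)

  expect_error(readBandTable(withr::local_tempfile(fileext = ".csv")),
               class = "habid_parse_error")
})
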