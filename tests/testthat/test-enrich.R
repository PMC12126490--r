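test_that("CPM and fold enrichment follow their defining formulas", {
  expect_equal(computeCPM(250, 5e6), 50)
  expect_equal(computeCPM(0, 123), 0)
  expect_equal(computeCPM(1e6, 1e6), 1e6)
  expect_error(computeCPM(5, 0), "library_total")

  expect_equal(locusFoldEnrichment(50, 25), 2)
  expect_equal(locusFoldEnrichment(0, 25), 0)
  expect_error(locusFoldEnrichment(3, 0), "positive")
  # the ratio cancels any common depth rescaling
  expect_equal(locusFoldEnrichment(computeCPM(30, 1e6), computeCPM(10, 2e6)),
               locusFoldEnrichment(computeCPM(30, 1e7), computeCPM(10, 2e7)))
})

test_that("input-coverage filter removes exactly the zero-input rows", {
  cc <- data.frame(locus_id = paste0("L", 1:6), dataset = "d1",
                   chip_count = c(5, 0, 7, 2, 9, 4),
                   input_count = c(0, 0, 1, 0, 3, 1))
  lc <- LocusCounts(cc, data.frame(dataset = "d1", chip_total = 1e6,
                                   input_total = 1e6))
  out <- filterLowCoverage(lc)
  expect_equal(nrow(countTable(out)), 3L)        # exactly k = 3 removed
  expect_setequal(countTable(out)$locus_id, c("L3", "L5", "L6"))
  expect_true(all(countTable(out)$input_count >= 1))  # input = 1 retained

  cc$input_count <- 0
  lc0 <- LocusCounts(cc, data.frame(dataset = "d1", chip_total = 1e6,
                                    input_total = 1e6))
  expect_warning(out0 <- filterLowCoverage(lc0), "no locus survived")
  expect_equal(nrow(countTable(out0)), 0L)
})

test_that("family median and z-score follow the stated conventions", {
  expect_equal(familyMedian(c(1, 2, 9)), 2)
  expect_equal(familyMedian(c(2, 4)), 3)
  expect_error(familyMedian(numeric(0), "famX"), "famX")
  # median robustness: 5 planted 100x outliers in 100 loci move it < 10%
  set.seed(42)
  base <- rlnorm(100, 0, 0.3)
  spiked <- c(base[1:95], base[96:100] * 100)
  expect_lt(abs(familyMedian(spiked) / familyMedian(base) - 1), 0.10)

  expect_equal(zscoreTransform(c(1, 2, 3)), c(-1, 0, 1))
  expect_error(zscoreTransform(c(4, 4, 4), "ds9"), "ds9")
  # normalization identity on random vectors
  for (i in 1:10) {
    z <- zscoreTransform(rlnorm(sample(3:50, 1)))
    expect_lt(abs(mean(z)), 1e-12)
    expect_lt(abs(sd(z) - 1), 1e-12)
  }
})

test_that("Spearman-rank clustering has the stated distance geometry", {
  m <- rbind(a = c(1, 5, 3, 8, 2),
             b = c(1, 5, 3, 8, 2),        # identical to a
             c = c(2, 26, 10, 65, 5),     # monotone transform of a
             d = c(8, 2, 5, 1, 7))        # reverse ranking of a
  hc <- clusterMatrix(m, "families")
  d <- as.matrix(stats::cophenetic(hc))
  expect_equal(d["a", "b"], 0)
  # rank invariance: monotone transform merges at height 0 too
  expect_equal(d["a", "c"], 0)
  # reversed ranking sits at Spearman rho = -1, distance 2
  rho <- cor(m["a", ], m["d", ], method = "spearman")
  expect_equal(1 - rho, 2)
  expect_gte(max(hc$height), 2 - 1e-9)

  mm <- rbind(a = c(1, 2, 3), b = c(5, 5, 5))
  expect_error(clusterMatrix(mm, "families"), "b")
})

test_that("pipeline equals a straight-line brute-force recomputation", {
  cfg <- simulationConfig(
    seed = 21, n_families = 4, loci_per_family = 30, genome_length = 5e6,
    enrichment_factors = list(
      d1 = setNames(c(1, 2, 4, 8), sprintf("family_%02d", 1:4)),
      d2 = 1.5),
    library_sizes = list(d1 = list(chip = 2e6, input = 1e6),
                         d2 = list(chip = 5e5, input = 8e5)),
    input_mean = 5, orphan_fraction = 0.5)  # low mean: filter actually fires
  ann <- simulateRepeatAnnotation(cfg)
  cnt <- simulateCountTable(ann, cfg)
  expect_lte(nrow(countTable(cnt)), 500)

  fe <- suppressWarnings(runEnrichmentPipeline(ann, cnt, cluster = FALSE))
  gr <- annotationRanges(ann)
  fam_of <- setNames(as.character(GenomicRanges::mcols(gr)$family),
                     GenomicRanges::mcols(gr)$locus_id)
  oracle <- bruteForceEnrichment(countTable(cnt), libraryTotals(cnt), fam_of)
  expect_equal(rawMedian(fe), oracle$raw, tolerance = 1e-12)
  expect_equal(zscores(fe), oracle$z, tolerance = 1e-12)
})

test_that("z-scores are invariant to rescaling library totals", {
  cfg <- simulationConfig(seed = 8, n_families = 5, loci_per_family = 25,
                          genome_length = 5e6)
  ann <- simulateRepeatAnnotation(cfg)
  cnt <- simulateCountTable(ann, cfg)
  fe1 <- runEnrichmentPipeline(ann, cnt, cluster = FALSE)
  lt <- libraryTotals(cnt)
  lt$chip_total <- lt$chip_total * 10
  lt$input_total <- lt$input_total * 10
  fe2 <- runEnrichmentPipeline(ann, LocusCounts(countTable(cnt), lt),
                               cluster = FALSE)
  expect_equal(zscores(fe1), zscores(fe2), tolerance = 1e-12)
  # raw medians scale by the chip/input rescaling ratio (here 1), so equal too
  expect_equal(rawMedian(fe1), rawMedian(fe2), tolerance = 1e-12)
})

test_that("raw family median is monotone in the planted enrichment factor", {
  fams <- sprintf("family_%02d", 1:3)
  med_at <- function(f) {
    cfg <- simulationConfig(
      seed = 13, n_families = 3, loci_per_family = 200, genome_length = 2e7,
      enrichment_factors = list(d1 = setNames(c(f, 1, 1), fams)),
      library_sizes = list(d1 = list(chip = 1e6, input = 1e6)),
      orphan_fraction = 1)
    ann <- simulateRepeatAnnotation(cfg)
    rawMedian(runEnrichmentPipeline(ann, simulateCountTable(ann, cfg),
                                    cluster = FALSE))["family_01", "d1"]
  }
  meds <- vapply(c(1, 2, 4, 8), med_at, numeric(1))
  expect_true(all(diff(meds) >= 0))
})

test_that("a single planted enrichment dominates the z-score column", {
  fams <- sprintf("family_%02d", 1:6)
  cfg <- simulationConfig(
    seed = 17, n_families = 6, loci_per_family = 100, genome_length = 2e7,
    enrichment_factors = list(d1 = setNames(c(4, rep(1, 5)), fams)),
    library_sizes = list(d1 = list(chip = 1e6, input = 1e6)))
  ann <- simulateRepeatAnnotation(cfg)
  fe <- runEnrichmentPipeline(ann, simulateCountTable(ann, cfg), cluster = FALSE)
  expect_equal(names(which.max(zscores(fe)[, "d1"])), "family_01")

  # null: no family is consistently extreme across seeds
  top <- vapply(1:3, function(s) {
    cfgn <- simulationConfig(seed = s, n_families = 6, loci_per_family = 50,
                             genome_length = 2e7)
    annn <- simulateRepeatAnnotation(cfgn)
    names(which.max(zscores(runEnrichmentPipeline(
      annn, simulateCountTable(annn, cfgn), cluster = FALSE))[, "chip1"]))
  }, character(1))
  expect_gt(length(unique(top)), 1)
})
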