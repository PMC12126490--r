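test_that("LTR dedup keeps the 5' LTR per integration and all orphans", {
  ann <- makeToyAnnotation()
  anchors <- dedupLtrs(ann)
  # i1 (full-length, +): only its 5' LTR, anchored at the start
  a1 <- anchors[anchors$integration_id == "i1", ]
  expect_equal(nrow(a1), 1)
  expect_equal(a1$position, 100)           # 0-based start of L1
  # i3 (full-length, -): 5' LTR is the right-most segment, anchored at its end
  a3 <- anchors[anchors$integration_id == "i3", ]
  expect_equal(nrow(a3), 1)
  expect_equal(a3$position, 17700)
  # orphan retained as its own anchor; k + m anchors in total
  expect_true("i2" %in% anchors$integration_id)
  expect_equal(nrow(anchors), 3)           # 2 full-length + 1 orphan

  # malformed annotation: two 5' LTRs in one integration
  gr <- annotationRanges(ann)
  bad <- gr
  S4Vectors::mcols(bad)$role[S4Vectors::mcols(bad)$role == "LTR3"] <- "LTR5"
  expect_error(RepeatAnnotation(bad), "two 5' LTR")
})

test_that("dedup equals the brute-force per-integration rule on random annotations", {
  cfg <- simulationConfig(seed = 31, n_families = 8, loci_per_family = 150,
                          genome_length = 6e7, orphan_fraction = 0.35)
  ann <- simulateRepeatAnnotation(cfg)
  gr <- annotationRanges(ann)
  expect_gte(length(gr), 1000)
  mc <- GenomicRanges::mcols(gr)
  df <- data.frame(start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   strand = as.character(GenomicRanges::strand(gr)),
                   role = as.character(mc$role),
                   integration_id = as.character(mc$integration_id))
  is_ltr <- df$role %in% c("LTR5", "LTR3", "orphanLTR")
  keep <- bruteForceDedup(df[is_ltr, ])
  expected <- df[is_ltr, ][keep, ]
  anchors <- dedupLtrs(ann)
  o1 <- order(expected$start)
  o2 <- order(anchors$start)
  expect_equal(anchors$start[o2], expected$start[o1])
  expect_equal(anchors$position[o2],
               ifelse(expected$strand[o1] == "-", expected$end[o1],
                      expected$start[o1]))
})

test_that("profile matrix matches per-base brute-force averaging and masks edges", {
  set.seed(77)
  glen <- 100000
  cov <- list(chrT = runif(glen, 0, 5))
  anchors <- data.frame(
    chrom = "chrT",
    position = c(3000, 40000, 99000, 500),   # 99000 and 500 hit the edges
    strand = c("+", "-", "+", "-"),
    family = "famA", integration_id = paste0("i", 1:4),
    start = c(3000, 39650, 99000, 150), end = c(3350, 40000, 99350, 500))
  pm <- buildProfileMatrix(cov, anchors, 1500, 8000, 50, sort_rows = FALSE)
  expect_equal(ncol(profileValues(pm)), 190)   # (1500 + 8000) / 50
  for (i in 1:4) {
    expect_equal(profileValues(pm)[i, ],
                 bruteForceProfileRow(cov$chrT, anchors$position[i],
                                      anchors$strand[i], 1500, 8000, 50),
                 tolerance = 1e-12)
  }
  # out-of-genome bins are masked, not zeroed
  expect_true(anyNA(profileValues(pm)[3, ]))
  expect_true(anyNA(profileValues(pm)[4, ]))

  # uniform coverage: every unmasked cell equals the constant
  u <- buildProfileMatrix(list(chrT = rep(2.5, glen)), anchors[1:2, ],
                          1500, 8000, 50)
  vals <- profileValues(u)
  expect_true(all(vals[!is.na(vals)] == 2.5))
  expect_error(buildProfileMatrix(cov, transform(anchors, chrom = "chrX")),
               "chromosome")
})

test_that("average profile is a column mean with SEM, invariant to row order", {
  m1 <- matrix(c(1, 2, 3, 4), 1)
  pm1 <- new("ProfileMatrix", values = m1,
             anchors = data.frame(chrom = "c", position = 0, strand = "+",
                                  family = "f", integration_id = "i"),
             windowUp = 100L, windowDown = 100L, binSize = 50L)
  expect_equal(averageProfile(pm1)$mean, c(1, 2, 3, 4))

  m2 <- rbind(c(1, 2, 3, 4), c(3, 2, 5, 0))
  anc2 <- data.frame(chrom = "c", position = c(0, 10), strand = "+",
                     family = "f", integration_id = c("i", "j"))
  pm2 <- new("ProfileMatrix", values = m2, anchors = anc2,
             windowUp = 100L, windowDown = 100L, binSize = 50L)
  ap <- averageProfile(pm2)
  expect_equal(ap$mean, c(2, 2, 4, 2))
  pm2r <- new("ProfileMatrix", values = m2[2:1, ], anchors = anc2[2:1, ],
              windowUp = 100L, windowDown = 100L, binSize = 50L)
  expect_equal(averageProfile(pm2r)$mean, ap$mean)
  expect_equal(ap$sem[1], sd(c(1, 3)) / sqrt(2))
})

test_that("average profiles are invariant under genome reflection", {
  set.seed(5)
  glen <- 50000
  cov <- list(chrT = runif(glen))
  anchors <- data.frame(chrom = "chrT", position = c(20000, 31000),
                        strand = c("+", "-"), family = "famA",
                        integration_id = c("i1", "i2"),
                        start = c(20000, 30650), end = c(20350, 31000))
  flipped <- data.frame(chrom = "chrT", position = glen - anchors$position,
                        strand = c("-", "+"), family = "famA",
                        integration_id = anchors$integration_id,
                        start = glen - anchors$end, end = glen - anchors$start)
  ap1 <- averageProfile(buildProfileMatrix(cov, anchors, 1500, 8000, 50))
  ap2 <- averageProfile(buildProfileMatrix(list(chrT = rev(cov$chrT)),
                                           flipped, 1500, 8000, 50))
  expect_equal(ap1$mean, ap2$mean, tolerance = 1e-12)
})

test_that("differential LTR test gives exact small-sample p and BH adjustment", {
  # worked example: U = 0, exact two-sided p = 2 / C(6,3) = 0.1
  res <- ltrDifferentialTest(c(1, 2, 3), c(4, 5, 6), rep("famA", 3))
  expect_equal(res$p, 0.1, tolerance = 1e-12)
  # identical multisets: symmetric null, p = 1
  res2 <- ltrDifferentialTest(c(2, 4, 6, 8), c(2, 4, 6, 8), rep("famA", 4))
  expect_equal(res2$p, 1)

  # BH column equals manual step-up across the tested family set
  set.seed(19)
  fam <- rep(sprintf("f%d", 1:5), each = 12)
  a <- rnbinom(60, mu = 20, size = 10)
  b <- rnbinom(60, mu = 20 / ifelse(fam == "f1", 4, 1), size = 10)
  res3 <- ltrDifferentialTest(a, b, fam)
  expect_equal(res3$p_adj, bruteForceBH(res3$p), tolerance = 1e-12)
  expect_equal(bruteForceBH(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_error(ltrDifferentialTest(1:3, numeric(0),
                                   list(rep("fX", 3), character(0))), "fX")
})

test_that("fragment counting hits every overlapping LTR once", {
  anchors <- data.frame(chrom = "chrT", position = c(100, 1000),
                        strand = "+", family = "famA",
                        integration_id = c("i1", "i2"),
                        start = c(100, 1000), end = c(200, 1100))
  frags <- GenomicRanges::GRanges("chrT", IRanges::IRanges(
    start = c(150, 190, 195, 500, 1099), width = 10))
  expect_equal(countInLtrs(anchors, frags), c(3L, 1L))
})
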