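test_that("a planted satellite array is recovered with period and span accuracy", {
  set.seed(41)
  monomer <- randomDna(200)
  s <- randomDna(500000)
  arrStart <- 200001L
  substr(s, arrStart, arrStart + 200L * 500L - 1L) <-
    strrep(monomer, 500)
  g <- Biostrings::DNAStringSet(c(c1 = s))
  arr <- findTandemArrays(g)
  expect_equal(length(arr), 1L)
  expect_lte(abs(arr$period - 200L), 2L)
  expect_lte(abs(start(arr) - arrStart), 200L)
  expect_lte(abs(end(arr) - (arrStart + 100000L - 1L)), 200L)

  ## repeat-free chromosome: no arrays at defaults
  g0 <- Biostrings::DNAStringSet(c(c1 = randomDna(300000)))
  expect_length(findTandemArrays(g0), 0L)
})

test_that("two distant planted arrays are reported as disjoint arrays", {
  set.seed(43)
  mono1 <- randomDna(150); mono2 <- randomDna(300)
  s <- randomDna(2400000)
  substr(s, 100001, 100000 + 150 * 200) <- strrep(mono1, 200)
  substr(s, 1300001, 1300000 + 300 * 120) <- strrep(mono2, 120)
  g <- Biostrings::DNAStringSet(c(c1 = s))
  arr <- findTandemArrays(g)
  expect_equal(length(arr), 2L)
  expect_gt(start(arr)[2] - end(arr)[1], 1000000L)
})

test_that("array clustering matches brute-force single linkage", {
  mkArr <- function(starts, ends) {
    GenomicRanges::GRanges("c1", IRanges::IRanges(starts, ends),
      period = 100L, copies = 10L, purity = 1,
      monomer = strrep("A", 100))
  }
  ## the gap between the two arrays is 49,999 bases: merged at or above
  ## the threshold, split below it
  a <- mkArr(c(1, 60000), c(10000, 70000))
  expect_equal(length(clusterArrays(a, clusterGap = 100000L)), 1L)
  expect_equal(length(clusterArrays(a, clusterGap = 49999L)), 1L)
  expect_equal(length(clusterArrays(a, clusterGap = 49998L)), 2L)

  set.seed(15)
  for (i in 1:300) {
    n <- sample(2:12, 1)
    st <- sort(sample.int(1e6, n))
    en <- st + sample(100:5000, n, replace = TRUE)
    gap <- sample(c(1000L, 10000L, 100000L), 1)
    cl <- clusterArrays(mkArr(st, en), clusterGap = gap)
    grp <- oracleSingleLinkage(st, en, gap)
    expect_equal(length(cl), length(unique(grp)))
    expect_equal(sum(cl$nArrays), n)
  }
})

test_that("cluster coverage and dominant monomer are computed exactly", {
  a <- GenomicRanges::GRanges("c1",
    IRanges::IRanges(c(1, 2001), c(1000, 3000)),
    period = c(100L, 100L), copies = c(10L, 10L), purity = c(1, 1),
    monomer = c(strrep("AC", 50), strrep("AG", 50)))
  cl <- clusterArrays(a, clusterGap = 5000L)
  expect_equal(length(cl), 1L)
  expect_equal(cl$arrayCoverage, 2000 / 3000)
  expect_equal(cl$nArrays, 2L)
})

test_that("centromere calling takes the best-scoring qualifying cluster", {
  g <- Biostrings::DNAStringSet(c(c1 = strrep("A", 600000)))
  cl <- GenomicRanges::GRanges("c1",
    IRanges::IRanges(c(1, 500000), c(100000, 540000)),
    nArrays = c(5L, 2L), arrayCoverage = c(0.9, 0.8),
    dominantMonomer = c("A", "C"), dominantPeriod = c(100L, 100L))
  cen <- callCentromeres(g, cl, minExtent = 20000L)
  expect_equal(length(granges(cen)), 1L)
  expect_equal(start(granges(cen)), 1L)   # 100 kb * 0.9 beats 40 kb * 0.8

  ## min extent excludes short clusters entirely
  cenBig <- callCentromeres(g, cl, minExtent = 200000L)
  expect_length(granges(cenBig), 0L)
})

test_that("fixture centromeres reciprocally overlap the planted truth by >= 80%", {
  sim <- fixtureSim()
  cen <- fixtureCentromeres()
  cg <- granges(cen)
  truth <- simTruth(sim)$centromeres
  expect_equal(length(cg), 9L)
  m <- match(as.character(GenomicRanges::seqnames(cg)),
             as.character(GenomicRanges::seqnames(truth)))
  expect_false(anyNA(m))
  ov <- GenomicRanges::pintersect(GenomicRanges::granges(cg),
                                  GenomicRanges::granges(truth[m]))
  rec <- pmin(width(ov) / width(cg), width(ov) / width(truth[m]))
  expect_true(all(rec >= 0.8))
})

test_that("centromere calls mirror under reverse complementation", {
  sim <- simulateAssembly(smallSim(seed = 37L, ltrScale = 0))
  g <- simGenome(sim)
  cen <- callCentromeres(g, clusterArrays(findTandemArrays(g)))
  grc <- Biostrings::reverseComplement(g)
  names(grc) <- names(g)
  cenRc <- callCentromeres(grc, clusterArrays(findTandemArrays(grc)))
  a <- granges(cen); b <- granges(cenRc)
  expect_equal(length(a), length(b))
  lens <- setNames(width(g), names(g))
  for (i in seq_along(a)) {
    nm <- as.character(GenomicRanges::seqnames(a)[i])
    j <- which(as.character(GenomicRanges::seqnames(b)) == nm)
    mirrorStart <- lens[[nm]] - end(b)[j] + 1L
    mirrorEnd <- lens[[nm]] - start(b)[j] + 1L
    ## spans mirror within one monomer of slack at each boundary
    expect_lte(abs(start(a)[i] - mirrorStart), a$period[i])
    expect_lte(abs(end(a)[i] - mirrorEnd), a$period[i])
  }
})

test_that("retro density trend peaks where features concentrate", {
  feats <- GenomicRanges::GRanges("c1",
    IRanges::IRanges(seq(500001, 540000, by = 2000), width = 1500))
  prof <- retroDensityProfile(feats, 1000000L, window = 100000L,
                              trendWindows = 1L)
  expect_equal(which.max(prof$density), 6L)
  expect_equal(which.max(prof$trend), 6L)
  ## smoothing keeps the peak adjacent to the loaded window
  prof3 <- retroDensityProfile(feats, 1000000L, window = 100000L,
                               trendWindows = 3L)
  expect_true(which.max(prof3$trend) %in% 5:7)
  ## densities are coverage fractions
  expect_true(all(prof$density >= 0 & prof$density <= 1))
})

test_that("trend maximum localizes an enriched centromere across seeds", {
  ## position-only simulation of the enrichment placement rule: factor 5
  ## over a 200-kb centromere in a 2-Mb chromosome, 300 elements
  set.seed(55)
  L <- 2000000; cenLo <- 900001; cenHi <- 1100000
  Lc <- cenHi - cenLo + 1; Lnc <- L - Lc
  f <- 5
  pCen <- f * Lc / (f * Lc + Lnc)
  hits <- 0L
  for (s in 1:100) {
    inCen <- runif(300) < pCen
    pos <- ifelse(inCen, sample(cenLo:cenHi, 300, TRUE),
                  sample.int(L, 300, TRUE))
    feats <- GenomicRanges::GRanges("c1",
      IRanges::IRanges(pos, width = 1000))
    prof <- retroDensityProfile(feats, L, window = 20000L,
                                trendWindows = 5L)
    peak <- which.max(prof$trend)
    if (prof$windowStart[peak] <= cenHi + 20000 &&
        prof$windowEnd[peak] >= cenLo - 20000) hits <- hits + 1L
  }
  expect_gte(hits, 95L)
})

test_that("uniform features rarely support a small centromere call", {
  set.seed(56)
  L <- 2000000
  callLo <- 970001; callHi <- 1030000   # 60-kb call
  supported <- 0L
  for (s in 1:100) {
    pos <- sample.int(L, 300, TRUE)
    feats <- GenomicRanges::GRanges("c1",
      IRanges::IRanges(pos, width = 1000))
    prof <- retroDensityProfile(feats, L, window = 20000L,
                                trendWindows = 5L)
    peak <- which.max(prof$trend)
    if (prof$windowStart[peak] <= callHi + 20000 &&
        prof$windowEnd[peak] >= callLo - 20000) supported <- supported + 1L
  }
  expect_lte(supported, 10L)
})
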