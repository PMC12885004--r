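test_that("one-tailed Fisher matches hand enumeration on reference tables", {
  expect_equal(fisherOneTailed(1, 0, 0, 1), 0.5)
  expect_equal(fisherOneTailed(5, 0, 0, 5), 1 / 252, tolerance = 1e-12)
  expect_equal(fisherOneTailed(2, 2, 2, 2), 53 / 70, tolerance = 1e-12)
  ## degenerate margins return 1 by convention
  expect_equal(fisherOneTailed(0, 0, 5, 5), 1)
  expect_equal(fisherOneTailed(0, 5, 0, 5), 1)
  expect_error(fisherOneTailed(-1, 0, 0, 1), "non-negative")
})

test_that("Fisher equals exhaustive hypergeometric enumeration for all N <= 60", {
  mismatches <- 0L
  for (N in 2:60) for (K in 1:(N - 1)) for (n in 1:(N - 1)) {
    lo <- max(0, K + n - N)
    hi <- min(K, n)
    for (a in lo:hi) {
      p <- fisherOneTailed(a, K - a, n - a, N - K - n + a)
      p0 <- oracleFisherTail(a, K - a, n - a, N - K - n + a)
      if (abs(p - p0) > 1e-9 * max(p0, 1e-12)) mismatches <- mismatches + 1L
    }
  }
  expect_equal(mismatches, 0L)
})

test_that("Fisher p-values are monotone in the enriched cell and stable at scale", {
  ## fixed margins: increasing a never increases p
  set.seed(71)
  for (i in 1:50) {
    N <- sample(20:200, 1)
    K <- sample(5:(N - 5), 1)
    n <- sample(5:(N - 5), 1)
    lo <- max(0, K + n - N); hi <- min(K, n)
    ps <- vapply(lo:hi, function(a)
      fisherOneTailed(a, K - a, n - a, N - K - n + a), 0)
    expect_true(all(diff(ps) <= 1e-12))
  }
  ## symmetry: p_greater + p_less - P(X = a) = 1 at the observed table
  for (i in 1:20) {
    a <- sample(0:20, 1); b <- sample(0:20, 1)
    cc <- sample(0:20, 1); d <- sample(0:20, 1)
    if ((a + b) == 0 || (a + cc) == 0 || b + d == 0 || cc + d == 0) next
    pG <- fisherOneTailed(a, b, cc, d)
    pL <- fisherOneTailed(cc, d, a, b)   # depletion = enrichment of the swap
    pEq <- stats::dhyper(a, a + b, cc + d, a + cc)
    expect_equal(pG + pL - pEq, 1, tolerance = 1e-9)
  }
  ## large-margin stability against the closed-form tail
  p <- fisherOneTailed(1200, 4000 - 1200, 800, 96000 - 800)
  p0 <- stats::phyper(1199, 4000, 96000, 2000, lower.tail = FALSE)
  expect_equal(p, p0, tolerance = 1e-10)
})

test_that("partition occupancy apportions bases exactly and counts by majority", {
  lens <- c(c1 = 100000)
  cen <- GenomicRanges::GRanges("c1", IRanges::IRanges(10001, 20000))
  el <- GenomicRanges::GRanges("c1",
    IRanges::IRanges(c(12001, 19401, 30001), width = 1000),
    id = c("in", "straddle", "out"))
  dm <- list(`in` = "D", straddle = "D", out = "D")
  occ <- partitionOccupancy(el, dm, cen, lens)
  row <- occ$perDomain
  expect_equal(row$lenCen, 1000 + 600)     # full + 600 of the straddler
  expect_equal(row$lenNon, 400 + 1000)
  expect_equal(row$countCen, 2L)           # majority rule: 600/1000 > half
  expect_equal(row$countNon, 1L)
  expect_equal(occ$totals$cenLength, 10000)
  expect_equal(occ$totals$cenLength + occ$totals$nonLength,
               occ$totals$genomeLength)

  elBad <- GenomicRanges::GRanges("cX", IRanges::IRanges(1, 10), id = "x")
  expect_error(partitionOccupancy(elBad, list(x = "D"), cen, lens),
               "unknown chromosome")
})

test_that("occupancy conserves bases against a per-base oracle on random fixtures", {
  set.seed(81)
  for (i in 1:25) {
    L <- 50000L
    lens <- c(c1 = L)
    cenStart <- sample.int(L - 10000L, 1)
    cen <- GenomicRanges::GRanges("c1",
      IRanges::IRanges(cenStart, cenStart + sample(2000:8000, 1)))
    n <- sample(5:30, 1)
    st <- sample.int(L - 600L, n)
    el <- GenomicRanges::GRanges("c1",
      IRanges::IRanges(st, width = sample(100:500, n, TRUE)),
      id = paste0("e", seq_len(n)))
    dm <- setNames(as.list(rep("D", n)), el$id)
    occ <- partitionOccupancy(el, dm, cen, lens)
    ## per-base oracle
    inCen <- logical(L)
    inCen[start(cen):min(end(cen), L)] <- TRUE
    covered <- integer(L)
    for (j in seq_len(n)) {
      covered[start(el)[j]:end(el)[j]] <- covered[start(el)[j]:end(el)[j]] + 1L
    }
    ## conservation holds per element (elements may overlap each other)
    expect_equal(occ$perDomain$lenCen + occ$perDomain$lenNon,
                 sum(width(el)))
    perElemCen <- vapply(seq_len(n), function(j)
      sum(inCen[start(el)[j]:end(el)[j]]), 0L)
    expect_equal(occ$perDomain$lenCen, sum(perElemCen))
  }
})

test_that("enrichment rows carry correct block-scale tests and ordering", {
  lens <- c(c1 = 2900000)
  cen <- GenomicRanges::GRanges("c1", IRanges::IRanges(1000001, 1024000))
  ## all 20 domain elements centromeric, 20 domain-free elements outside
  el <- GenomicRanges::GRanges("c1", IRanges::IRanges(
    c(seq(1000001, by = 1200, length.out = 20),
      seq(2000001, by = 1200, length.out = 20)), width = 1000),
    id = paste0("e", 1:40))
  dm <- c(setNames(as.list(rep("D", 20)), paste0("e", 1:20)),
          setNames(rep(list(character(0)), 20), paste0("e", 21:40)))
  occ <- partitionOccupancy(el, dm, cen, lens)
  res <- enrichmentTable(occ)
  tab <- enrichmentRows(res)
  expect_equal(tab$countCen, 20L)
  expect_equal(tab$countNon, 0L)
  ## closed form: all 20 domain elements among the 20 centromeric of 40
  expect_equal(tab$pCount, 1 / choose(40, 20), tolerance = 1e-9)
  expect_true(tab$significant)
  expect_equal(tab$propCen, 20000 / 24000)

  expect_error(
    enrichmentTable(list(perDomain = occ$perDomain,
                         totals = list(cenLength = 0, nonLength = 10,
                                       genomeLength = 10),
                         nCenElements = 0, nNonElements = 0)),
    "zero-length partition")
})

test_that("a tenfold occupancy contrast is significant in >= 95 of 100 seeds", {
  ## factor-10 contrast: domain covers ~10% of a 25-kb centromere and ~1%
  ## of the rest of a 2.9-Mb genome, element placement resampled per seed
  set.seed(91)
  lens <- c(c1 = 2900000)
  cen <- GenomicRanges::GRanges("c1", IRanges::IRanges(1000001, 1025000))
  nSig <- 0L
  for (s in 1:100) {
    cenSt <- sample(1000001:1024000, 3)          # ~3 kb of 25 kb ~ 12%
    nonSt <- sample(c(1:970000, 1060000:2870000), 29)  # ~29 kb of 2.875 Mb ~ 1%
    el <- GenomicRanges::GRanges("c1",
      IRanges::IRanges(c(cenSt, nonSt), width = 1000),
      id = paste0("e", seq_len(32)))
    dm <- setNames(as.list(rep("D", 32)), el$id)
    occ <- partitionOccupancy(el, dm, cen, lens)
    res <- enrichmentTable(occ)
    if (enrichmentRows(res)$significant[1]) nSig <- nSig + 1L
  }
  expect_gte(nSig, 95L)
})

test_that("identical sparse occupancy keeps p at or above 0.5 in >= 90 of 100 seeds", {
  ## sparse-domain null: 8 elements uniform over the genome, centromeres
  ## covering ~0.8% — most seeds place no element in a centromere
  set.seed(92)
  lens <- c(c1 = 29000000)
  cen <- GenomicRanges::GRanges("c1", IRanges::IRanges(14000001, 14240000))
  nNull <- 0L
  for (s in 1:100) {
    st <- sample.int(29000000 - 2000, 8)
    el <- GenomicRanges::GRanges("c1", IRanges::IRanges(st, width = 2000),
                                 id = paste0("e", 1:8))
    dm <- setNames(as.list(rep("D", 8)), el$id)
    occ <- partitionOccupancy(el, dm, cen, lens)
    tab <- enrichmentRows(enrichmentTable(occ))
    if (tab$pLength >= 0.5 && tab$pCount >= 0.5) nNull <- nNull + 1L
  }
  expect_gte(nNull, 90L)
})

test_that("the top-enriched report keeps only significant rows, ordered by p", {
  mkOcc <- function(lens) {
    list(perDomain = data.frame(
           label = paste0("D", seq_along(lens)),
           lenCen = lens, lenNon = 1000,
           countCen = pmax(1L, as.integer(lens / 1000)), countNon = 1L),
         totals = list(cenLength = 50000, nonLength = 950000,
                       genomeLength = 1e6),
         nCenElements = 60L, nNonElements = 60L)
  }
  res <- enrichmentTable(mkOcc(c(30000, 25000, 20000, 15000, 12000,
                                 9000, 7000, 5000)))
  top <- topEnriched(res, k = 6)
  expect_lte(nrow(top), 6L)
  expect_true(all(top$significant))
  expect_true(!is.unsorted(top$pLength))

  none <- enrichmentTable(mkOcc(c(10, 12)))
  t0 <- topEnriched(none)
  expect_equal(nrow(t0), 0L)
  expect_match(attr(t0, "note"), "no significantly enriched")
})

test_that("strongly planted Tat/Phygy/Selgy fixtures surface in the report", {
  sim <- fixtureSim()
  scan <- fixtureScan()
  el <- fixtureElements()
  truth <- simTruth(sim)$centromeres
  occ <- partitionOccupancy(el, scan$map, truth, simGenome(sim))
  res <- enrichmentTable(occ)
  top <- topEnriched(res)
  ## the strongly enriched Gypsy lineages dominate the significant set
  expect_true(any(grepl("^Tat", top$label)) || "Selgy" %in% top$label ||
              "Phygy" %in% top$label)
  ## unenriched Copia lineages never outrank the planted Gypsy lineages
  tab <- enrichmentRows(res)
  pTat <- min(tab$pLength[grepl("^Tat|Selgy", tab$label)])
  pCop <- min(tab$pLength[tab$label %in% c("Bryco", "SIRE")])
  expect_lt(pTat, pCop)
})
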