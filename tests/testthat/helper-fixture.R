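## Memoized desk-scale fixture: the nine-chromosome synthetic assembly at
## 1% of the published chromosome lengths (telomere copy numbers kept at
## their printed values), generated once per test run.

.fixtureEnv <- new.env(parent = emptyenv())

fixtureSim <- function() {
  if (!exists("sim", envir = .fixtureEnv))
    assign("sim", simulateAssembly(simConfigScaled(seed = 1L)),
           envir = .fixtureEnv)
  get("sim", envir = .fixtureEnv)
}

fixtureTelomeres <- function() {
  if (!exists("telo", envir = .fixtureEnv))
    assign("telo", callTelomeres(simGenome(fixtureSim())),
           envir = .fixtureEnv)
  get("telo", envir = .fixtureEnv)
}

fixtureCentromeres <- function() {
  if (!exists("cen", envir = .fixtureEnv)) {
    sim <- fixtureSim()
    arrays <- findTandemArrays(simGenome(sim))
    assign("arrays", arrays, envir = .fixtureEnv)
    assign("cen",
           callCentromeres(simGenome(sim), clusterArrays(arrays)),
           envir = .fixtureEnv)
  }
  get("cen", envir = .fixtureEnv)
}

fixtureScan <- function() {
  if (!exists("scan", envir = .fixtureEnv)) {
    sim <- fixtureSim()
    feats <- simTruth(sim)$ltr
    feats$type <- "LTR_retrotransposon"
    el <- extractElements(simGenome(sim), feats)
    assign("elements", el, envir = .fixtureEnv)
    assign("scan", scanElements(el, readDomainLibrary()),
           envir = .fixtureEnv)
  }
  get("scan", envir = .fixtureEnv)
}

fixtureElements <- function() {
  fixtureScan()
  get("elements", envir = .fixtureEnv)
}

## a small two-chromosome simulation for cheap unit tests
smallSim <- function(seed = 7L, ltrScale = 0.3) {
  ch <- data.frame(
    name = c("c1", "c2"), length = c(600000L, 500000L),
    leftMotif = c("CCCTAAA", "ACGCAGC"), leftCopies = c(100L, 80L),
    rightMotif = c("TTTAGGG", "TGCGTCG"), rightCopies = c(90L, 70L),
    cenStart = c(300000L, 200000L), cenLength = c(40000L, 30000L),
    stringsAsFactors = FALSE)
  plan <- if (ltrScale > 0) defaultLtrPlan(countScale = ltrScale) else NULL
  simConfig(ch, seed = seed, ltrPlan = plan)
}
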