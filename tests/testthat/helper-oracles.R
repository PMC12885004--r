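## Independent oracles used by the property tests. Each re-derives the
## expected quantity by a route independent of the implementation under
## test (brute force, enumeration, direct codon lookup).

randomDna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

## N50 by explicit sort-and-accumulate
oracleN50 <- function(lens) {
  lens <- sort(lens, decreasing = TRUE)
  cs <- cumsum(lens)
  lens[which(cs >= sum(lens) / 2)[1]]
}

## canonical motif by explicit enumeration of all rotations of the motif
## and of its reverse complement
oracleCanonical <- function(m) {
  rot <- function(s) {
    n <- nchar(s)
    vapply(0:(n - 1), function(i) paste0(substr(s, i + 1, n),
                                         substr(s, 1, i)), "")
  }
  rc <- chartr("ACGT", "TGCA", paste(rev(strsplit(m, "")[[1]]),
                                     collapse = ""))
  min(c(rot(m), rot(rc)))
}

## translate one forward-strand frame by direct codon lookup
oracleTranslateFrame <- function(seq, frame) {
  code <- Biostrings::GENETIC_CODE
  n <- nchar(seq) - frame
  n <- n - n %% 3
  if (n < 3) return("")
  codons <- substring(seq, frame + seq(1, n, 3), frame + seq(3, n, 3))
  paste(unname(code[codons]), collapse = "")
}

## single-linkage clustering of intervals by transitive closure
oracleSingleLinkage <- function(starts, ends, gap) {
  n <- length(starts)
  grp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (grp[i] != grp[j]) {
        g <- max(starts[i], starts[j]) - min(ends[i], ends[j]) - 1
        if (g <= gap) {
          grp[grp == grp[j]] <- grp[i]
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  grp
}

## upper-tail hypergeometric probability via choose()
oracleFisherTail <- function(a, b, c, d) {
  N <- a + b + c + d; K <- a + b; n <- a + c
  if (K == 0 || n == 0 || K == N || n == N) return(1)
  j <- a:min(K, n)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

revcompStr <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}
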