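## random row-stochastic matrix (uses the current RNG stream)
randomStochastic <- function(k = 4) {
  m <- matrix(rexp(k * k), k, k)
  m / rowSums(m)
}

## pooled 3-year matrix without the renormalization warning noise in tests
eq3 <- function() suppressWarnings(threeYearDisabilityMatrix())

## build a panel data.frame from an explicit origin -> destination count table
panelFromCounts <- function(countMat) {
  s0 <- s1 <- integer(0)
  for (i in seq_len(nrow(countMat)))
    for (j in seq_len(ncol(countMat))) {
      n <- countMat[i, j]
      s0 <- c(s0, rep(i, n)); s1 <- c(s1, rep(j, n))
    }
  data.frame(state0 = s0, state1 = s1)
}
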