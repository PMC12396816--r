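# shared fixture builders; everything is generated in code at test time

NUC <- c("A", "C", "G", "T")

# a RatePrediction with constant rate and one fixed CSP row everywhere
constantPrediction <- function(L, rate, cspRow) {
  new("RatePrediction",
    rates = rep(rate, L),
    csp = matrix(cspRow, L, 4, byrow = TRUE),
    flagged = rep(FALSE, L)
  )
}

# uniform-rate pair fixture: L sites, first m mutated A->C
uniformPair <- function(L, m, t = NULL) {
  parent <- strrep("A", L)
  child <- paste0(strrep("C", m), strrep("A", L - m))
  if (is.null(t)) PcpSet(parent, child) else PcpSet(parent, child, branchLength = t)
}

# brute-force all-pairs AUROC oracle (ties counted 1/2)
bruteForceAuroc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# tiny training set simulated from a 3-mer truth
smallSim <- function(nPairs = 6, L = 60, t = 0.3, seedTm = 2, seedSim = 5) {
  tm <- randomTrueModel(3, seed = seedTm)
  list(tm = tm, pcps = simulateDataset(simConfig(nPairs, L, t, seed = seedSim), tm))
}

# exact expectation of average precision under a uniformly random ranking of
# n items with p positives; converges to the prevalence p/n as n grows.
# Derivation: P(item at rank k is positive) = p/n and, conditionally, the
# other p-1 positives are uniform over the remaining n-1 ranks, so
# E[precision at k] = (1 + (k-1)(p-1)/(n-1)) / k.
exactRandomAP <- function(n, p) {
  k <- seq_len(n)
  sum((1 + (p - 1) * (k - 1) / (n - 1)) / k) / n
}

# third-codon-position fourfold-degenerate codons, frozen by hand from the
# standard genetic code (independent of the implementation's derivation)
FOURFOLD_PREFIXES <- c("CT", "GT", "TC", "CC", "AC", "GC", "CG", "GG")
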