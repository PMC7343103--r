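# Independent oracles, deliberately computed by different routes than the
# package implementation.

EPS0_ORACLE <- 8.854e-12

# complex relative permittivity by direct arithmetic
oracleComplexPerm <- function(eps, sig, f) {
  complex(real = eps, imaginary = -sig / (2 * pi * f * EPS0_ORACLE))
}

# finite-thickness two-layer shelled sphere: membrane of thickness d with
# relative permittivity C*d/eps0 and conductivity G*d, cytoplasm inside,
# combined with the classic shelled-sphere mixing formula
oracleFiniteShellPerm <- function(radius, C, G, epsCyt, sigCyt, f, d = 5e-9) {
  epsMem <- oracleComplexPerm(C * d / EPS0_ORACLE, G * d, f)
  epsC <- oracleComplexPerm(epsCyt, sigCyt, f)
  g3 <- (radius / (radius - d))^3
  E <- (epsC - epsMem) / (epsC + 2 * epsMem)
  epsMem * (g3 + 2 * E) / (g3 - E)
}

oracleFiniteShellCM <- function(radius, C, G, epsCyt, sigCyt,
                                epsMed, sigMed, f, d = 5e-9) {
  ep <- oracleFiniteShellPerm(radius, C, G, epsCyt, sigCyt, f, d)
  em <- oracleComplexPerm(epsMed, sigMed, f)
  Re((ep - em) / (ep + 2 * em))
}

# thin-shell closed-form crossover
oracleCrossoverClosedForm <- function(radius, C, sigMed) {
  sqrt(2) * sigMed / (2 * pi * radius * C)
}

# brute-force sort-and-slice band means
oracleBandMeans <- function(values, freqs, mask, nLow, nHigh,
                            mode = "by_frequency") {
  v <- values[mask]
  f <- freqs[mask]
  if (mode == "by_frequency") {
    sf <- sort(f)
    lowSet <- v[f %in% sf[seq_len(nLow)]]
    highSet <- v[f %in% rev(sf)[seq_len(nHigh)]]
  } else {
    sv <- sort(v)
    lowSet <- sv[seq_len(nLow)]
    highSet <- rev(sv)[seq_len(nHigh)]
  }
  c(low = mean(lowSet), high = mean(highSet))
}

# brute-force Youden optimum over all candidate thresholds (midpoints of
# consecutive sorted MDVs plus points beyond the extremes)
oracleYoudenOptimum <- function(mdv, truth) {
  v <- sort(unique(mdv))
  cand <- c(v[1] - 1, (v[-1] + v[-length(v)]) / 2, v[length(v)] + 1)
  you <- vapply(cand, function(t) {
    pred <- ifelse(mdv < t, "cancer", "control")
    se <- sum(pred == "cancer" & truth == "cancer") / sum(truth == "cancer")
    sp <- sum(pred == "control" & truth == "control") / sum(truth == "control")
    se + sp - 1
  }, numeric(1))
  max(you)
}

# textbook pooled-variance two-sample t statistic and two-tailed p
oraclePooledT <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  p <- 2 * pt(-abs(t), df = na + nb - 2)
  c(t = t, p = p)
}
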