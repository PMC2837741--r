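# Independent oracles and small fixture builders used across the suite.

# Brute-force Cohen's kappa: expand an integer 3x3 table into two rater
# vectors and compute agreement statistics from the raw pairs. Shares no
# code with the ConfusionTable path.
bruteKappa <- function(tab) {
  r1 <- integer(0); r2 <- integer(0)
  for (i in 1:3) for (j in 1:3) {
    r1 <- c(r1, rep(i, tab[i, j]))
    r2 <- c(r2, rep(j, tab[i, j]))
  }
  po <- mean(r1 == r2)
  pc <- sum(vapply(1:3, function(k) mean(r1 == k) * mean(r2 == k),
                   numeric(1)))
  (po - pc) / (1 - pc)
}

# random nondegenerate integer 3x3 table
randomIntTable <- function(maxCell = 30) {
  repeat {
    tab <- matrix(sample(0:maxCell, 9, replace = TRUE), 3, 3)
    pc <- sum(rowSums(tab) * colSums(tab)) / sum(tab)^2
    if (sum(tab) > 0 && (1 - pc) > 1e-6) return(tab)
  }
}

# one-hot posterior rows for hard calls
onehotProbs <- function(calls) {
  p <- matrix(0, length(calls), 3)
  p[cbind(seq_along(calls), calls + 1L)] <- 1
  p
}

# a ConfusionTable from an integer table (rows = imputed, cols = true):
# reconstruct (truth, posterior) pairs and run the tabulation under test
tableToConfusion <- function(tab) {
  truth <- integer(0); imputed <- integer(0)
  for (i in 1:3) for (j in 1:3) {
    imputed <- c(imputed, rep(i - 1L, tab[i, j]))
    truth <- c(truth, rep(j - 1L, tab[i, j]))
  }
  confusionTable(truth, onehotProbs(imputed))
}

# soft-blend posteriors toward the realized genotype distribution
softBlendProbs <- function(truth, eps) {
  pi <- vapply(0:2, function(g) mean(truth == g), numeric(1))
  (1 - eps) * onehotProbs(truth) +
    eps * matrix(pi, length(truth), 3, byrow = TRUE)
}

# random 2x3 genotype count table with at least one case and control
# and nonzero dosage variance
randomTrendTable <- function(maxCell = 25) {
  repeat {
    tab <- matrix(sample(0:maxCell, 6, replace = TRUE), 2, 3)
    d <- rep(0:2, colSums(tab))
    if (all(rowSums(tab) > 0) && var(d) > 0) return(tab)
  }
}

# expand a 2x3 table (rows control/case, cols genotype 0/1/2) to
# individual-level dosages and phenotype
expandTrendTable <- function(tab) {
  y <- integer(0); d <- integer(0)
  for (r in 1:2) for (g in 1:3) {
    y <- c(y, rep(r - 1L, tab[r, g]))
    d <- c(d, rep(g - 1L, tab[r, g]))
  }
  list(y = y, dosage = d)
}
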