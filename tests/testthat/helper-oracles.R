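# Independent reference implementations used as oracles.

# Brute-force OPTICS core distances straight from the definition, using a
# full distance matrix (the point itself counts at distance 0).
bfCoreDistances <- function(samples, MinPts, eps) {
  D <- as.matrix(dist(samples))
  vapply(seq_len(nrow(D)), function(o) {
    d <- D[o, ]
    if (sum(d <= eps) < MinPts) NA_real_ else sort(d)[MinPts]
  }, numeric(1))
}

# Brute-force OPTICS ordering: plain array scans, no queue structure.
bfOptics <- function(samples, MinPts, eps) {
  D <- as.matrix(dist(samples))
  n <- nrow(D)
  core <- bfCoreDistances(samples, MinPts, eps)
  processed <- rep(FALSE, n)
  tentative <- rep(Inf, n)
  ord <- integer(0)
  reach <- numeric(0)
  visit <- function(i, r) {
    processed[i] <<- TRUE
    ord <<- c(ord, i)
    reach <<- c(reach, r)
    if (!is.na(core[i])) {
      for (j in which(D[i, ] <= eps)) {
        if (!processed[j]) {
          tentative[j] <<- min(tentative[j], max(core[i], D[i, j]))
        }
      }
    }
  }
  for (s in seq_len(n)) {
    if (processed[s]) next
    visit(s, NA_real_)
    repeat {
      cand <- which(!processed & is.finite(tentative))
      if (!length(cand)) break
      i <- cand[which.min(tentative[cand])]
      visit(i, tentative[i])
    }
  }
  list(order = ord, reach = reach, core = core)
}

# Adjusted Rand index from the pair-counting formula.
adjustedRand <- function(a, b) {
  tab <- table(a, b)
  nij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  n2 <- choose(sum(tab), 2)
  expected <- ai * bj / n2
  (nij - expected) / ((ai + bj) / 2 - expected)
}

# Dice coefficient of two binary masks.
diceCoef <- function(a, b) {
  2 * sum(a * b) / (sum(a) + sum(b))
}

iouCoef <- function(a, b) {
  sum(a * b) / sum((a + b) > 0)
}

# Brute-force severity-threshold search written against table(), kept
# independent of the package's entropy code.
bfSeverityFit <- function(counts, labels) {
  vals <- sort(unique(counts))
  best <- NULL
  for (t1 in vals) for (t2 in vals) {
    if (t2 <= t1) next
    bins <- cut(counts, breaks = c(-Inf, t1, t2, Inf), labels = FALSE)
    H <- 0
    for (b in 1:3) {
      sel <- bins == b
      if (!any(sel)) next
      p <- prop.table(table(labels[sel]))
      H <- H + mean(sel) * (-sum(p * log2(p)))
    }
    if (is.null(best) || H < best$H - 1e-12) best <- list(t1 = t1, t2 = t2, H = H)
  }
  best
}

# Small cached fundus fixtures shared across test files.
.fixtureEnv <- new.env()
fixtureFundus <- function(class, seed, size = 64L, ...) {
  key <- paste(class, seed, size, sep = "_")
  if (is.null(.fixtureEnv[[key]])) {
    .fixtureEnv[[key]] <- generateFundus(
      retinopipe:::randomFundusSpec(class, seed, size, size, ...))
  }
  .fixtureEnv[[key]]
}
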