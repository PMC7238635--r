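# Independent oracles and shared fixtures.  Oracles deliberately avoid the
# package's own computational paths: the label-map oracle enumerates
# pairings recursively, the k-mer oracle counts literal strings, and the
# Fisher oracle sums the full hypergeometric support.

# --- exhaustive monotone-pairing oracle for the label-map aligner ---------
# Best score over all monotone pairings with >= minPairs pairs, under the
# same scoring model (pair bonus, capped sizing penalty, per-skip miss
# penalty).  Returns -Inf when no qualifying pairing exists.
bruteLabelAlignScore <- function(q, r, p) {
  best <- -Inf
  pen <- function(i1, j1, i2, j2) {
    dq <- q[i2] - q[i1]; dr <- r[j2] - r[j1]
    mi <- max((dq + dr) / 2, 1)
    min((dq - dr)^2 / (p$sdCoeff^2 * mi), p$svCap) +
      p$missPenalty * ((i2 - i1 - 1) + (j2 - j1 - 1))
  }
  rec <- function(iPrev, jPrev, score, npairs) {
    if (npairs >= p$minPairs && score > best) best <<- score
    i0 <- if (npairs == 0) 1 else iPrev + 1
    j0 <- if (npairs == 0) 1 else jPrev + 1
    if (i0 > length(q) || j0 > length(r)) return()
    for (i2 in i0:length(q)) for (j2 in j0:length(r)) {
      s2 <- score + p$pairBonus -
        (if (npairs > 0) pen(iPrev, jPrev, i2, j2) else 0)
      rec(i2, j2, s2, npairs + 1)
    }
  }
  rec(0, 0, 0, 0)
  best
}

# Best score over both orientations, as the aligner reports it.
bruteLabelAlignBoth <- function(qm, rm, p) {
  qrev <- sort(qm@length - rev(qm@labels) + 1)
  max(bruteLabelAlignScore(qm@labels, rm@labels, p),
      bruteLabelAlignScore(qrev, rm@labels, p))
}

# --- literal k-mer dictionary oracle for unique k-mer fraction ------------
dictionaryUniqueFraction <- function(seqs, k) {
  all <- character(0)
  for (s in seqs) {
    n <- nchar(s)
    if (n < k) next
    km <- substring(s, 1:(n - k + 1), k:n)
    ok <- !grepl("N", km, fixed = TRUE)
    km <- km[ok]
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(km)))
    all <- c(all, pmin(km, rc))
  }
  tab <- table(all)
  sum(tab == 1) / length(all)
}

# --- full-support hypergeometric enumeration oracle for Fisher's test -----
fisherEnumOracle <- function(x11, x12, x21, x22) {
  m <- x11 + x12; n <- x21 + x22; k <- x11 + x21
  support <- max(0, k - n):min(k, m)
  pr <- vapply(support, function(i)
    choose(m, i) * choose(n, k - i) / choose(m + n, k), 0)
  obs <- pr[support == x11]
  sum(pr[pr <= obs * (1 + 1e-7)])
}

# --- cumulative-sum N50/N90 oracle ----------------------------------------
n50Oracle <- function(lens, q) {
  lens <- sort(lens, decreasing = TRUE)
  lens[which(cumsum(lens) >= q * sum(lens))[1]]
}

# --- shared fixtures (memoised across test files) -------------------------
.fixtures <- new.env(parent = emptyenv())

# Small full-featured bundle (3 x 1 Mb chromosomes, all planted events).
miniBundle <- function(seed = 1) {
  key <- paste0("bundle", seed)
  if (is.null(.fixtures[[key]])) {
    cfg <- simConfig(seed = seed, scale = 0.2)
    .fixtures[[key]] <- suppressWarnings(simulateBundle(cfg))
  }
  .fixtures[[key]]
}

# One-chromosome simulation for annotation/simulator tests.
tinySim <- function(seed = 7) {
  key <- paste0("tiny", seed)
  if (is.null(.fixtures[[key]])) {
    cfg <- simConfig(seed = seed, scale = 0.2, nChromosomes = 1L)
    .fixtures[[key]] <- suppressWarnings(simulateGenome(cfg))
  }
  .fixtures[[key]]
}

# A random label map with roughly uniform spacing.
randomLabelMap <- function(id, n, meanSpacing = 4000) {
  lab <- cumsum(stats::runif(n, 0.5 * meanSpacing, 1.5 * meanSpacing))
  labelMap(id, max(lab) + meanSpacing, lab, source = "optical")
}
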