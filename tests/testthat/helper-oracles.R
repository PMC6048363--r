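# Independent oracles used across the suite. Each is a plain, direct
# implementation kept deliberately separate from the package internals.

# explicit-loop two-way median polish (row sweeps first, medians moved
# into the overall term), the brute-force reference for medianPolish()
median_polish_oracle <- function(x, max_iter = 200L, tol = 1e-9) {
  overall <- 0
  re <- rep(0, nrow(x)); ce <- rep(0, ncol(x))
  r <- x
  old <- sum(abs(r), na.rm = TRUE)
  for (it in seq_len(max_iter)) {
    for (i in seq_len(nrow(x))) {
      m <- median(r[i, ], na.rm = TRUE)
      r[i, ] <- r[i, ] - m
      re[i] <- re[i] + m
    }
    d <- median(ce); ce <- ce - d; overall <- overall + d
    for (j in seq_len(ncol(x))) {
      m <- median(r[, j], na.rm = TRUE)
      r[, j] <- r[, j] - m
      ce[j] <- ce[j] + m
    }
    d <- median(re); re <- re - d; overall <- overall + d
    new <- sum(abs(r), na.rm = TRUE)
    if (abs(old - new) <= tol) break
    old <- new
  }
  list(overall = overall, row_effects = re, col_effects = ce,
       residuals = r)
}

# hypergeometric enumeration of Fisher's exact test on a 2x2 table
# (rows = with/without, cols = group A/B); one-sided = enrichment of
# cell [1,1]; two-sided = sum of outcomes no more probable
fisher_oracle <- function(a, b, c, d, alternative = "greater") {
  K <- a + b   # row-1 margin
  n <- a + c   # col-1 margin
  N <- a + b + c + d
  lo <- max(0L, n - (N - K)); hi <- min(K, n)
  k <- lo:hi
  pk <- choose(K, k) * choose(N - K, n - k) / choose(N, n)
  if (alternative == "greater") sum(pk[k >= a])
  else sum(pk[pk <= pk[k == a] * (1 + 1e-7)])
}

# textbook pooled-variance two-sample t
pooled_t_oracle <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
  (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
}

# direct running-sum GSEA enrichment score (explicit loop)
gsea_es_oracle <- function(scores, hit_idx, weight = 1) {
  n <- length(scores)
  nr <- sum(abs(scores[hit_idx])^weight)
  run <- 0; best <- 0
  for (i in seq_len(n)) {
    if (i %in% hit_idx) run <- run + abs(scores[i])^weight / nr
    else run <- run - 1 / (n - length(hit_idx))
    if (abs(run) > abs(best)) best <- run
  }
  best
}

# exhaustive PWM score-tail enumeration over all 4^w words
pwm_tail_oracle <- function(motif) {
  p <- motifProbs(motif)
  bg <- motifBackground(motif)
  s <- log2(p / bg)
  w <- ncol(p)
  words <- as.matrix(expand.grid(rep(list(1:4), w)))
  sc <- numeric(nrow(words)); pr <- numeric(nrow(words))
  for (i in seq_len(nrow(words))) {
    sc[i] <- sum(s[cbind(words[i, ], seq_len(w))])
    pr[i] <- prod(bg[words[i, ]])
  }
  function(thr) sum(pr[sc >= thr - 1e-9])
}

# adjusted Rand index between two partitions
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  nij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  n2 <- choose(sum(tab), 2)
  expected <- ai * bj / n2
  (nij - expected) / ((ai + bj) / 2 - expected)
}

# B-score table for synthetic screens: stacked over readouts
stacked_bscores <- function(plates, readouts) {
  do.call(rbind, lapply(readouts, function(r) bScore(plates, r)))
}
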