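# Independent oracles used across the suite.  These deliberately take the
# naive route (loops, explicit enumeration) so they share no code with the
# implementation they check.

# Benjamini-Hochberg by explicit sort-and-cummin
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  ranked <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(ranked)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# one-sided hypergeometric over-representation by full enumeration with
# binomial coefficients (universe small enough for exact choose())
hyper_enum_oracle <- function(k, a, b, universe) {
  kk <- k:min(a, b)
  sum(choose(b, kk) * choose(universe - b, a - kk)) / choose(universe, a)
}

# per-position rescoring PWM scan, both strands, one promoter at a time
naive_scan_oracle <- function(pwm, seqs, threshold, bg = rep(0.25, 4)) {
  lo <- log(pwm$prob / bg)
  w <- ncol(lo)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  score_one <- function(chars, m) {
    L <- length(chars)
    if (L < w) return(0L)
    hits <- 0L
    for (i in 1:(L - w + 1)) {
      s <- 0
      for (j in 1:w) {
        b <- chars[i + j - 1]
        if (!b %in% c("A", "C", "G", "T")) { s <- -Inf; break }
        s <- s + m[b, j]
      }
      if (s >= threshold) hits <- hits + 1L
    }
    hits
  }
  vapply(seqs, function(sq) {
    chars <- strsplit(sq, "")[[1]]
    rc <- rev(unname(comp[chars]))
    rc[is.na(rc)] <- "N"
    # reverse strand: score the reverse complement of the sequence with the
    # forward matrix (equivalent to scanning the minus strand)
    score_one(chars, lo) + score_one(rc, lo)
  }, integer(1))
}

# exact-consensus PWM for a given motif string
consensus_pwm <- function(motif, id = "CONS", tf = "CONSTF") {
  bases <- c("A", "C", "G", "T")
  m <- matrix(0, 4, nchar(motif), dimnames = list(bases, NULL))
  ch <- strsplit(motif, "")[[1]]
  for (j in seq_along(ch)) m[ch[j], j] <- 100
  new_pwm(id, tf, m)
}

# random i.i.d. promoter sequences
random_seqs <- function(n, len, seed, p = rep(0.25, 4)) {
  set.seed(seed)
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE, prob = p),
          collapse = ""), "")
}

# mean silhouette over a 2-cluster labelling from coordinates
silhouette_mean <- function(coords, labels) {
  d <- as.matrix(dist(coords))
  vals <- vapply(seq_len(nrow(d)), function(i) {
    own <- labels == labels[i]
    a <- mean(d[i, own & seq_len(nrow(d)) != i])
    b <- mean(d[i, !own])
    (b - a) / max(a, b)
  }, numeric(1))
  mean(vals)
}
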