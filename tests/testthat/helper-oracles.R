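# Independent brute-force oracles. These deliberately share no code with the
# package: ranks are counted by comparison, BH is the textbook step-up loop,
# the t upper tail is numerically integrated from the density, and the
# global alignment is enumerated recursively.

brute_rank <- function(v) {
  vapply(seq_along(v), function(i) {
    sum(v < v[i]) + (sum(v == v[i]) + 1) / 2
  }, numeric(1))
}

brute_spearman <- function(x, y) {
  rx <- brute_rank(x)
  ry <- brute_rank(y)
  dx <- rx - mean(rx)
  dy <- ry - mean(ry)
  denom <- sqrt(sum(dx^2) * sum(dy^2))
  if (denom == 0) return(NA_real_)
  sum(dx * dy) / denom
}

brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  sorted <- p[o]
  adj_sorted <- vapply(seq_len(m), function(i) {
    min(1, min(sorted[i:m] * m / (i:m)))
  }, numeric(1))
  adj <- numeric(m)
  adj[o] <- adj_sorted
  adj
}

# upper-tail Student t probability by numeric integration of the density
brute_t_upper <- function(t, df) {
  dens <- function(u) {
    exp(lgamma((df + 1) / 2) - lgamma(df / 2)) / sqrt(df * pi) *
      (1 + u^2 / df)^(-(df + 1) / 2)
  }
  if (t >= 0) {
    stats::integrate(dens, t, Inf, rel.tol = 1e-12)$value
  } else {
    1 - stats::integrate(dens, -t, Inf, rel.tol = 1e-12)$value
  }
}

# exhaustive global alignment (match +1, mismatch 0, gap -1); returns the
# best score and, among co-optimal alignments, the attained identities
brute_align <- function(a, b) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  best <- new.env()
  best$score <- -Inf
  best$identities <- numeric(0)
  rec <- function(i, j, score, match, cols) {
    if (i > length(A) && j > length(B)) {
      if (score > best$score) {
        best$score <- score
        best$identities <- match / cols
      } else if (score == best$score) {
        best$identities <- c(best$identities, match / cols)
      }
      return(invisible())
    }
    if (i <= length(A) && j <= length(B)) {
      hit <- A[i] == B[j]
      rec(i + 1, j + 1, score + hit, match + hit, cols + 1)
    }
    if (i <= length(A)) rec(i + 1, j, score - 1, match, cols + 1)
    if (j <= length(B)) rec(i, j + 1, score - 1, match, cols + 1)
  }
  rec(1, 1, 0, 0, 0)
  list(score = best$score, identities = unique(best$identities))
}
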