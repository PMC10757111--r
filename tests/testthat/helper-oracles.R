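# Independent brute-force oracles used across test files.

extdata <- function(name) system.file("extdata", name, package = "ithmm")

# double-median MAD, written independently of the package's scaled_mad
brute_scaled_mad <- function(x, constant = 1.4826) {
  n <- length(x)
  med <- if (n %% 2) sort(x)[(n + 1) / 2] else mean(sort(x)[n / 2 + 0:1])
  dev <- sort(abs(x - med))
  m2 <- if (n %% 2) dev[(n + 1) / 2] else mean(dev[n / 2 + 0:1])
  constant * m2
}

# enumerate every mutation-overlapping window of the given lengths
brute_tiles <- function(wt, mut, interval, lengths = 8:10) {
  out <- character(0)
  if (length(interval) == 0) return(out)
  for (L in lengths) {
    if (nchar(mut) < L) next
    for (s in seq_len(nchar(mut) - L + 1)) {
      if (s > interval[2] || s + L - 1 < interval[1]) next
      mp <- substr(mut, s, s + L - 1)
      wp <- if (nchar(wt) == nchar(mut)) substr(wt, s, s + L - 1) else NA
      if (!is.na(wp) && wp == mp) next
      out <- c(out, mp)
    }
  }
  unique(out)
}

# best gapless local alignment score by exhaustive substring enumeration
brute_gapless_score <- function(a, b, sub) {
  best <- 0
  for (la in seq_len(nchar(a))) for (sa in seq_len(nchar(a) - la + 1)) {
    for (sb in seq_len(max(0, nchar(b) - la + 1))) {
      aa <- strsplit(substr(a, sa, sa + la - 1), "")[[1]]
      bb <- strsplit(substr(b, sb, sb + la - 1), "")[[1]]
      best <- max(best, sum(sub[cbind(aa, bb)]))
    }
  }
  best
}

# two-group log-rank chi-square from the standard O-E/V hypergeometric table
brute_logrank <- function(time, event, group) {
  g <- as.integer(as.factor(group))
  times <- sort(unique(time[event == 1]))
  o_minus_e <- 0; v <- 0
  for (t in times) {
    at_risk <- time >= t
    n <- sum(at_risk); n1 <- sum(at_risk & g == 1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g == 1)
    e1 <- d * n1 / n
    o_minus_e <- o_minus_e + (d1 - e1)
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (o_minus_e)^2 / v
}

random_peptide <- function(n, alphabet = strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]])
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
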