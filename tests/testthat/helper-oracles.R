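# Independent brute-force oracles used across test files. These stay
# deliberately naive: enumeration, quadratic scans, and textbook
# formulas, never the package's own code paths.

# exhaustive score distribution of a motif under iid background:
# enumerates all 4^L sequences, scoring in the same left-to-right
# accumulation order as the scanner
enumerate_scores <- function(log_odds, background = rep(0.25, 4)) {
  L <- nrow(log_odds)
  grid <- as.matrix(expand.grid(rep(list(1:4), L)))
  score <- numeric(nrow(grid))
  prob <- numeric(nrow(grid)) + 1
  for (j in seq_len(L)) {
    score <- score + log_odds[j, grid[, j]]
    prob <- prob * background[grid[, j]]
  }
  list(score = score, prob = prob)
}

# smallest achievable score whose exact tail probability is <= p;
# ties (scores equal up to accumulation noise) are grouped before the
# tail is formed, and the group minimum is reported
enum_threshold <- function(log_odds, p, background = rep(0.25, 4)) {
  en <- enumerate_scores(log_odds, background)
  o <- order(en$score)
  s <- en$score[o]; pr <- en$prob[o]
  grp <- cumsum(c(TRUE, diff(s) > 1e-9))
  g_min <- s[!duplicated(grp)]
  g_prob <- as.vector(rowsum(pr, grp))
  tail <- rev(cumsum(rev(g_prob)))
  ok <- which(tail <= p)
  if (!length(ok)) return(Inf)
  unname(g_min[min(ok)])
}

# exact tail probability P(score >= s) with the same tie tolerance
enum_tail <- function(log_odds, s, background = rep(0.25, 4)) {
  en <- enumerate_scores(log_odds, background)
  sum(en$prob[en$score >= s - 1e-9])
}

# naive per-offset scoring of one strand of a character sequence
naive_scan_strand <- function(chars, log_odds) {
  L <- nrow(log_odds)
  codes <- match(chars, c("A", "C", "G", "T"))
  n_off <- length(chars) - L + 1
  vapply(seq_len(n_off), function(o) {
    acc <- 0
    for (j in seq_len(L)) {
      c <- codes[o + j - 1]
      acc <- acc + if (is.na(c)) -Inf else log_odds[j, c]
    }
    acc
  }, numeric(1))
}

revcomp_chars <- function(chars) {
  rev(c(A = "T", C = "G", G = "C", T = "A", N = "N")[chars])
}

# textbook BH step-up, written independently of stats::p.adjust
stepup_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# Spearman rho from the rank formula with average ranks
rank_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# two-sided Fisher exact p by exhaustive hypergeometric tail summation
fisher_enum <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  support <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- stats::dhyper(support, c1, n - c1, r1)
  p_obs <- stats::dhyper(a, c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# exact permutation p for the two-sample rank-sum statistic
permutation_ranksum_p <- function(x, y) {
  all <- c(x, y)
  n <- length(all); nx <- length(x)
  r <- rank(all)
  obs <- sum(r[seq_len(nx)])
  combs <- utils::combn(n, nx)
  stats <- apply(combs, 2, function(idx) sum(r[idx]))
  mu <- nx * (n + 1) / 2
  mean(abs(stats - mu) >= abs(obs - mu) - 1e-9)
}

# small random scenario used by several files
tiny_scenario <- function(seed, n_cpgs = 400, ...) {
  simulation_scenario("runx1", n_cpgs = n_cpgs, rng_seed = seed, ...)
}

random_pwm_counts <- function(L, seed) {
  set.seed(seed)
  matrix(stats::rpois(4 * L, 6), ncol = 4)
}
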