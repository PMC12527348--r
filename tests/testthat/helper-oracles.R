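# Independent literal-formula oracles used to check the statistical engine.
# These re-derive each statistic from its textbook definition and stay
# independent of the code paths they verify.

# Exact two-sided Wilcoxon rank-sum p by full enumeration of rank splits.
oracle_wilcoxon_exact <- function(a, b) {
  n1 <- length(a)
  r <- rank(c(a, b))
  combos <- utils::combn(n1 + length(b), n1)
  ws <- apply(combos, 2, function(idx) sum(r[idx])) - n1 * (n1 + 1) / 2
  w <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  min(1, 2 * min(mean(ws <= w), mean(ws >= w)))
}

# Student's t with pooled variance.
oracle_student_t <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  sp2 <- ((n1 - 1) * var(a) + (n2 - 1) * var(b)) / (n1 + n2 - 2)
  t <- (mean(b) - mean(a)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  list(statistic = t, p = 2 * pt(-abs(t), df), df = df)
}

# Welch's t with Satterthwaite df.
oracle_welch_t <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  v1 <- var(a) / n1; v2 <- var(b) / n2
  t <- (mean(b) - mean(a)) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  list(statistic = t, p = 2 * pt(-abs(t), df), df = df)
}

# One-way fixed-effects ANOVA F.
oracle_anova_f <- function(groups) {
  k <- length(groups)
  ns <- lengths(groups)
  N <- sum(ns)
  grand <- mean(unlist(groups))
  ssb <- sum(ns * (vapply(groups, mean, numeric(1)) - grand)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  f <- (ssb / (k - 1)) / (ssw / (N - k))
  list(statistic = f, p = pf(f, k - 1, N - k, lower.tail = FALSE))
}

# Welch's heteroscedastic ANOVA.
oracle_welch_anova <- function(groups) {
  k <- length(groups)
  ns <- lengths(groups)
  m <- vapply(groups, mean, numeric(1))
  w <- ns / vapply(groups, var, numeric(1))
  mw <- sum(w * m) / sum(w)
  a <- sum(w * (m - mw)^2) / (k - 1)
  lambda <- sum((1 - w / sum(w))^2 / (ns - 1))
  f <- a / (1 + 2 * (k - 2) * lambda / (k^2 - 1))
  df2 <- (k^2 - 1) / (3 * lambda)
  list(statistic = f, p = pf(f, k - 1, df2, lower.tail = FALSE))
}

# Median-centred Levene (Brown-Forsythe): one-way F on |y - median_g|.
oracle_levene_median <- function(groups) {
  z <- lapply(groups, function(g) abs(g - median(g)))
  oracle_anova_f(z)
}

# Kruskal-Wallis H with tie correction, chi-square p.
oracle_kruskal <- function(groups) {
  y <- unlist(groups)
  N <- length(y)
  r <- rank(y)
  idx <- rep(seq_along(groups), lengths(groups))
  rsum <- tapply(r, idx, sum)
  h <- 12 / (N * (N + 1)) * sum(rsum^2 / lengths(groups)) - 3 * (N + 1)
  ties <- table(y)
  h <- h / (1 - sum(ties^3 - ties) / (N^3 - N))
  list(statistic = h, p = pchisq(h, length(groups) - 1, lower.tail = FALSE))
}

# Step-by-step multiple-testing adjustments from their definitions.
oracle_adjust <- function(p, method) {
  m <- length(p)
  o <- order(p)
  ranked <- p[o]
  adj <- switch(
    method,
    bonferroni = pmin(1, p * m),
    holm = {
      a <- pmin(1, cummax((m - seq_len(m) + 1) * ranked))
      out <- numeric(m); out[o] <- a; out
    },
    hochberg = {
      a <- rev(pmin(1, cummin(rev((m - seq_len(m) + 1) * ranked))))
      out <- numeric(m); out[o] <- a; out
    },
    BH = {
      a <- rev(pmin(1, cummin(rev(m / seq_len(m) * ranked))))
      out <- numeric(m); out[o] <- a; out
    },
    BY = {
      cm <- sum(1 / seq_len(m))
      a <- rev(pmin(1, cummin(rev(cm * m / seq_len(m) * ranked))))
      out <- numeric(m); out[o] <- a; out
    }
  )
  adj
}
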