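# Independent brute-force oracles, deliberately naive and separate from the
# package's vectorized implementations.

oracle_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  num <- sum((x - mx) * (y - my))
  num / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

oracle_pearson_p <- function(r, n) {
  t <- r * sqrt(n - 2) / sqrt(1 - r^2)
  2 * (1 - pt(abs(t), n - 2))
}

oracle_student_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  list(t = t, df = na + nb - 2, p = 2 * (1 - pt(abs(t), na + nb - 2)))
}

# Upper-tail hypergeometric by explicit enumeration of overlap outcomes.
oracle_hyper_tail <- function(k, K, n, N) {
  js <- k:min(K, n)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# All permutations of 1..n (small n only).
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}

# Small helper: cohort + grouping + config in one go.
make_cohort <- function(seed = 1, ...) {
  d <- simulation_design(seed = seed, ...)
  co <- generate_cohort(d)
  list(cohort = co, grouping = sample_grouping(co$clinical))
}

tiny_expr <- function(values, hk = rownames(values)[1], scale = "normalized") {
  expr_matrix(values, hk, scale)
}
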