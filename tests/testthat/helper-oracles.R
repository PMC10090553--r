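# Independent from-definition oracles. These deliberately use explicit
# loops/sums over the defining formulas and share no code with the package
# implementations they check.

# Product-moment correlation straight from the definition.
oracle_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  num <- 0; dx <- 0; dy <- 0
  for (i in seq_len(n)) {
    num <- num + (x[i] - mx) * (y[i] - my)
    dx <- dx + (x[i] - mx)^2
    dy <- dy + (y[i] - my)^2
  }
  unname(num / sqrt(dx * dy))
}

# Spearman: midranks by counting, then the Pearson oracle.
oracle_midrank <- function(x) {
  n <- length(x)
  r <- numeric(n)
  for (i in seq_len(n)) {
    less <- sum(x < x[i])
    eq <- sum(x == x[i])
    r[i] <- less + (eq + 1) / 2
  }
  r
}

oracle_spearman <- function(x, y) {
  oracle_pearson(oracle_midrank(x), oracle_midrank(y))
}

# Running-sum enrichment score by walking every rank explicitly.
# profile: named numeric sorted descending; set: member symbols.
# Ties between the positive and negative extremum resolve to the positive
# one (the documented convention of the implementation under check).
oracle_es <- function(profile, set, weight_p) {
  genes <- names(profile)
  hit <- genes %in% set
  k <- sum(hit)
  N <- length(genes)
  stopifnot(k > 0, k < N)
  w <- abs(profile)^weight_p
  w_sum <- sum(w[hit])
  running <- 0
  walk <- numeric(N)
  for (i in seq_len(N)) {
    if (hit[i]) {
      running <- running +
        (if (w_sum > 0) w[i] / w_sum else 1 / k)
    } else {
      running <- running - 1 / (N - k)
    }
    walk[i] <- running
  }
  m_pos <- max(walk)
  m_neg <- min(walk)
  if (m_pos >= -m_neg - 1e-9) m_pos else m_neg
}

# Exact two-sided Mann-Whitney p by enumerating all group assignments.
oracle_ranksum_p <- function(v_hi, v_lo) {
  all_v <- c(v_hi, v_lo)
  n1 <- length(v_hi)
  idx <- utils::combn(length(all_v), n1)
  r <- rank(all_v)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  u_all <- apply(idx, 2, function(sel) sum(r[sel]) - n1 * (n1 + 1) / 2)
  mu <- n1 * length(v_lo) / 2
  mean(abs(u_all - mu) >= abs(u_obs - mu))
}

# Deterministic tiny matrix fixture used by several io tests.
tiny_matrix <- function() {
  m <- matrix(c(-0.5, 0.1, -0.3, 0.0), nrow = 2, byrow = TRUE,
              dimnames = list(c("RET", "ZBTB7A"), c("L1", "L2")))
  m
}
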