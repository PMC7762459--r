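# Independent oracle implementations used across test files. These are
# deliberately written from the closed forms, not by calling package code.

# Normal-Gamma marginal likelihood of a vector of values
ng_logml_oracle <- function(y, mu0 = 0, l0 = 0.1, a0 = 0.1, b0 = 0.1) {
  n <- length(y)
  if (n == 0) return(0)
  yb <- mean(y)
  ss <- sum((y - yb)^2)
  ln <- l0 + n
  an <- a0 + n / 2
  bn <- b0 + ss / 2 + l0 * n * (yb - mu0)^2 / (2 * ln)
  lgamma(an) - lgamma(a0) + a0 * log(b0) - an * log(bn) +
    0.5 * (log(l0) - log(ln)) - n / 2 * log(2 * pi)
}

# all set partitions of n items as restricted growth strings
all_set_partitions <- function(n) {
  out <- list()
  rec <- function(prefix, mx) {
    if (length(prefix) == n) {
      out[[length(out) + 1]] <<- prefix
      return()
    }
    for (v in 1:(mx + 1)) rec(c(prefix, v), max(mx, v))
  }
  rec(c(1L), 1L)
  out
}

# brute-force BH step-up: q_(i) = min_{j >= i} p_(j) * m / j
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- rev(cummin(rev(p[o] * m / seq_len(m))))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# independent running-sum implementation used as the ssGSEA oracle
ssgsea_oracle <- function(expr, set, w) {
  o <- order(expr, decreasing = TRUE)
  nm <- names(expr)[o]
  v <- expr[o]
  hit <- nm %in% set
  num <- abs(v)^w
  running <- 0
  total <- 0
  for (i in seq_along(v)) {
    if (hit[i]) running <- running + num[i] / sum(num[hit])
    else running <- running - 1 / sum(!hit)
    total <- total + running
  }
  unname(total)
}

# toy two-group cohort for selector tests
tiny_cohort <- function(seed = 1) {
  generate_cohort(sim_config(n_tumor = 30, n_normal = 30, n_genes = 150,
                             n_modules = 3, genes_per_module = 30,
                             decoys_per_platform = 4, tf_decoys = 3,
                             seed = seed))
}
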