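# Independent small-scale oracles, deliberately brute-force.

# Exact unsigned Stirling numbers of the first kind for small n, by the
# integer recurrence s(n, a) = (n-1) s(n-1, a) + s(n-1, a-1).
stirling_exact <- function(n_max) {
  s <- matrix(0, n_max, n_max)
  s[1, 1] <- 1
  if (n_max > 1) for (n in 2:n_max) {
    s[n, 1] <- (n - 1) * s[n - 1, 1]
    for (a in 2:n) s[n, a] <- (n - 1) * s[n - 1, a] + s[n - 1, a - 1]
  }
  s
}

# Brute-force K(D, A): enumerate every ancestor configuration {a_i} with
# 1 <= a_i <= n_i and sum a_i = A, summing prod_i s(n_i, a_i) s(a_i, 1) / s(n_i, 1).
brute_force_K <- function(abund, A) {
  s <- stirling_exact(max(abund))
  fact <- function(k) if (k == 0) 1 else prod(seq_len(k))
  configs <- expand.grid(lapply(abund, seq_len))
  configs <- configs[rowSums(configs) == A, , drop = FALSE]
  if (!nrow(configs)) return(0)
  sum(apply(configs, 1, function(a) {
    prod(vapply(seq_along(abund), function(i) {
      s[abund[i], a[i]] * fact(a[i] - 1) / fact(abund[i] - 1)
    }, numeric(1)))
  }))
}

# Small multi-sample OTU fixture with hand-set counts.
tiny_otu <- function() {
  otu_table(matrix(c(5L, 0L, 1L, 1L,
                     2L, 3L, 0L, 4L,
                     0L, 0L, 7L, 2L), nrow = 3, byrow = TRUE,
                   dimnames = list(c("s1", "s2", "s3"),
                                   c("t1", "t2", "t3", "t4"))))
}
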