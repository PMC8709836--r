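# Shared fixtures and independent oracles for the test suite.

fx <- load_fixtures()

# Breadth-first search over all reversal products: the brute-force oracle for
# reversal distance on small signed permutations. Independent of the
# iterative-deepening search under test.
oracle_reversal_distance <- function(perm, cap = 3) {
  key <- function(p) paste(p, collapse = ",")
  target <- key(seq_along(perm))
  if (key(perm) == target) return(0L)
  seen <- new.env(hash = TRUE)
  assign(key(perm), TRUE, envir = seen)
  frontier <- list(perm)
  for (d in seq_len(cap)) {
    nxt <- list()
    for (p in frontier) {
      n <- length(p)
      for (i in seq_len(n)) {
        for (j in i:n) {
          q <- p
          q[i:j] <- -rev(q[i:j])
          k <- key(q)
          if (k == target) return(d)
          if (is.null(seen[[k]])) {
            assign(k, TRUE, envir = seen)
            nxt[[length(nxt) + 1L]] <- q
          }
        }
      }
    }
    frontier <- nxt
  }
  Inf
}

# exact biallelic Hardy-Weinberg test by direct enumeration of heterozygote
# counts (Levene's conditional distribution), written independently of
# hw_exact_test's generic array enumeration
oracle_biallelic_exact <- function(n11, n12, n22) {
  n <- n11 + n12 + n22
  nA <- 2 * n11 + n12
  hets <- seq(nA %% 2, min(nA, 2 * n - nA), by = 2)
  lp <- vapply(hets, function(h) {
    h11 <- (nA - h) / 2
    h22 <- n - h11 - h
    lfactorial(n) - lfactorial(h11) - lfactorial(h) - lfactorial(h22) +
      h * log(2) + lfactorial(nA) + lfactorial(2 * n - nA) - lfactorial(2 * n)
  }, numeric(1))
  p_obs <- lp[hets == n12]
  sum(exp(lp[lp <= p_obs + 1e-9]))
}

# pairs of packaged sequences and their published/derived reversal distances
paper_distance_suite <- function() {
  data.frame(
    a = c("A1", "B1", "B2", "D1", "D1", "E1", "F1", "F1", "C1"),
    b = c("A2", "B2", "B3", "D2", "D3", "E2", "F3", "F2", "C2"),
    d = c(1, 1, 1, 1, 1, 1, 1, 2, 2),
    exact_required = c(rep(TRUE, 8), FALSE),  # C1-C2: published as complex, d >= 2
    stringsAsFactors = FALSE)
}
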