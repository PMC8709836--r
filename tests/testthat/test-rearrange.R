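test_that("published within-arm pairs have the expected reversal distances", {
  suite <- paper_distance_suite()
  for (r in seq_len(nrow(suite))) {
    res <- pool_compare(fx$pool, suite$a[r], suite$b[r])
    lbl <- paste(suite$a[r], suite$b[r])
    if (suite$exact_required[r]) {
      expect_true(res$exact, label = paste("exact", lbl))
      expect_equal(res$distance, suite$d[r], label = paste("distance", lbl))
    } else {
      expect_gte(res$distance, suite$d[r])
    }
    expected_class <- if (suite$d[r] == 1) "simple" else "complex"
    expect_equal(res$classification, expected_class, label = paste("class", lbl))
  }
})

test_that("identical sequences are at distance zero", {
  for (id in c("A1", "B2", "D1", "F1")) {
    m <- pool_sequence(fx$pool, id)
    res <- reversal_distance(
      to_signed_arrangement(m, m, fx$pool$catalogues[[m$arm]]))
    expect_equal(res$distance, 0)
    expect_equal(res$classification, "identical")
  }
  expect_equal(classify_pair(pool_sequence(fx$pool, "D1"),
                             pool_sequence(fx$pool, "D1"),
                             fx$pool$catalogues$D), "identical")
})

test_that("single-reversal breakpoints land on the published inverted blocks", {
  pool <- fx$pool
  bp <- single_reversal_breakpoints(pool_sequence(pool, "B1"),
                                    pool_sequence(pool, "B2"),
                                    pool$catalogues$B)
  expect_equal(unname(bp), c("22c", "23c"))
  bp <- single_reversal_breakpoints(pool_sequence(pool, "F1"),
                                    pool_sequence(pool, "F3"),
                                    pool$catalogues$F)
  expect_equal(unname(bp), c("22a", "22e"))
  # not defined for identical maps or complex pairs
  expect_null(single_reversal_breakpoints(pool_sequence(pool, "F1"),
                                          pool_sequence(pool, "F1"),
                                          pool$catalogues$F))
  expect_null(single_reversal_breakpoints(pool_sequence(pool, "F1"),
                                          pool_sequence(pool, "F2"),
                                          pool$catalogues$F))
})

test_that("the distance behaves as a metric on the packaged pool", {
  for (arm in c("A", "B", "C", "D", "E", "F")) {
    maps <- pool_arm(fx$pool, arm)
    cat_a <- fx$pool$catalogues[[arm]]
    ids <- vapply(maps, `[[`, "", "id")
    k <- length(maps)
    d <- matrix(0, k, k)
    for (i in seq_len(k)) for (j in seq_len(k)) {
      if (i != j) {
        d[i, j] <- reversal_distance(
          to_signed_arrangement(maps[[j]], maps[[i]], cat_a))$distance
      }
    }
    expect_equal(d, t(d), label = paste("symmetry, arm", arm))
    if (k >= 3) {
      for (i in 1:k) for (j in 1:k) for (l in 1:k) {
        expect_lte(d[i, l], d[i, j] + d[j, l])
      }
    }
  }
})

test_that("returned scenarios transform the reference into the target", {
  pool <- fx$pool
  pairs <- paper_distance_suite()
  for (r in seq_len(nrow(pairs))) {
    a <- pool_sequence(pool, pairs$a[r])
    b <- pool_sequence(pool, pairs$b[r])
    arr <- to_signed_arrangement(b, a, pool$catalogues[[a$arm]])
    res <- reversal_distance(arr)
    if (!res$exact) next
    got <- apply_scenario(seq_len(res$n_segments), res$scenario)
    expect_equal(abs(got), abs(arr$perm))
    free <- arr$ambiguous
    expect_equal(got[!free], arr$perm[!free])
  }
})

test_that("lone-band segments carry a free sign resolved by minimization", {
  pool <- fx$pool
  arr <- to_signed_arrangement(pool_sequence(pool, "A2"),
                               pool_sequence(pool, "A1"),
                               pool$catalogues$A)
  amb <- which(arr$ambiguous)
  expect_true(length(amb) >= 1)
  expect_true(any(vapply(arr$segments[abs(arr$perm[amb])],
                         function(s) "3i" %in% s, logical(1))))
})

test_that("planted reversals are recovered against the brute-force oracle", {
  set.seed(101)
  for (case in 1:15) {
    n <- sample(4:8, 1)
    k <- sample(1:2, 1)
    perm <- seq_len(n)
    for (r in seq_len(k)) {
      i <- sample(n - 1, 1); j <- sample((i + 1):n, 1)
      perm[i:j] <- -rev(perm[i:j])
    }
    d_pkg <- reversal_distance(perm)$distance
    d_bfs <- oracle_reversal_distance(perm, cap = 3)
    expect_lte(d_pkg, k)
    expect_equal(d_pkg, d_bfs)
  }
})

test_that("search beyond the depth cap reports an inexact lower bound", {
  # 7 elements fully reversed pairwise-disordered: needs many reversals
  perm <- c(3L, 1L, 5L, 2L, 7L, 4L, 6L)
  res <- reversal_distance(perm, max_d = 1)
  expect_false(res$exact)
  expect_gte(res$distance, 2)
  expect_null(res$scenario)
})
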