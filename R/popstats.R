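# Population data model: arm genotypes, allele frequencies, polymorphism
# indices, Hardy-Weinberg goodness of fit.
#
# Alternative banding sequences of one arm behave as alleles of one locus; a
# larva's arm genotype is an unordered pair of sequence ids, heterozygous
# when the ids differ. Heterozygous arms are visible as inversion loops and
# each heterozygous arm counts as ONE heterozygous inversion regardless of
# how many reversals separate the two sequences.

.sort_pair <- function(s1, s2) {
  # order by serial when both ids carry one, else lexicographically
  serial <- function(x) suppressWarnings(as.integer(sub("^.*[A-Ga-g]", "", x)))
  k1 <- serial(s1); k2 <- serial(s2)
  swap <- ifelse(!is.na(k1) & !is.na(k2) & k1 != k2, k1 > k2, s1 > s2)
  list(a = ifelse(swap, s2, s1), b = ifelse(swap, s1, s2))
}

#' Normalize a genotype label of the published dialect
#'
#' Accepts `"p'agiB1.2"` (shared base id, two serials) and
#' `"h'agiC1.p'agiC2"` (two full ids), returning the two full sequence ids.
#'
#' @param label genotype label.
#' @return character vector of length 2 (sorted by serial).
#' @export
parse_genotype_label <- function(label) {
  label <- .norm_apostrophe(label)
  parts <- strsplit(label, ".", fixed = TRUE)[[1]]
  if (length(parts) != 2) stop("malformed genotype label: ", label, call. = FALSE)
  s1 <- parts[1]
  s2 <- if (grepl("^[0-9]+$", parts[2])) {
    paste0(sub("[0-9]+$", "", parts[1]), parts[2])
  } else parts[2]
  p <- .sort_pair(s1, s2)
  c(p$a, p$b)
}

#' Construct a population sample
#'
#' Holds one collection site's karyotype data either at larva level (one row
#' per larva, one column per arm, genotypes as `"id1/id2"` strings) or as
#' aggregated per-arm genotype counts.
#'
#' @param code population code, e.g. `"NSK-SH"`.
#' @param n number of larvae.
#' @param counts optional data frame with columns `arm`, `seq1`, `seq2`,
#'   `count` (counts may also be frequencies summing to 1 per arm).
#' @param larvae optional data frame of larva-level genotypes, one column per
#'   arm.
#' @param b_chromosomes integer vector (per larva) or single carrier count.
#' @param meta optional list of site metadata.
#' @return object of class `population_sample`.
#' @export
population_sample <- function(code, n, counts = NULL, larvae = NULL,
                              b_chromosomes = 0, meta = NULL) {
  if (is.null(counts) && is.null(larvae)) {
    stop("need counts or larvae", call. = FALSE)
  }
  if (!is.null(larvae)) {
    stopifnot(nrow(larvae) == n)
    if (length(b_chromosomes) == 1) b_chromosomes <- rep(b_chromosomes, n)
  }
  if (!is.null(counts)) {
    stopifnot(all(c("arm", "seq1", "seq2", "count") %in% names(counts)))
    p <- .sort_pair(counts$seq1, counts$seq2)
    counts$seq1 <- p$a; counts$seq2 <- p$b
  }
  structure(list(code = code, n = n, counts = counts, larvae = larvae,
                 b_chromosomes = b_chromosomes, meta = meta),
            class = "population_sample")
}

.sample_counts <- function(sample) {
  if (!is.null(sample$counts)) return(sample$counts)
  lv <- sample$larvae
  out <- lapply(names(lv), function(arm) {
    tab <- table(lv[[arm]])
    parts <- strsplit(names(tab), "/", fixed = TRUE)
    data.frame(arm = arm,
               seq1 = vapply(parts, `[`, "", 1),
               seq2 = vapply(parts, `[`, "", 2),
               count = as.numeric(tab), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' @export
print.population_sample <- function(x, ...) {
  cat("Population", x$code, "- n =", x$n, "larvae",
      if (!is.null(x$larvae)) "(larva-level)" else "(aggregated)", "\n")
  invisible(x)
}

# ---- allele frequencies ----------------------------------------------------

#' Construct an allele-frequency table
#'
#' Per-arm banding-sequence frequency vectors for one population.
#'
#' @param population population code.
#' @param arms named list (by arm letter) of named numeric frequency vectors.
#' @param tol tolerance on each arm's frequency sum (use a printed-rounding
#'   tolerance, e.g. 0.01, for transcribed tables).
#' @return object of class `freq_table`.
#' @export
allele_frequency_table <- function(population, arms, tol = 1e-9) {
  for (a in names(arms)) {
    s <- sum(arms[[a]])
    if (abs(s - 1) > tol) {
      stop("frequencies of arm ", a, " in ", population, " sum to ", s,
           call. = FALSE)
    }
    if (any(arms[[a]] < 0)) stop("negative frequency in arm ", a, call. = FALSE)
  }
  structure(list(population = population, arms = arms), class = "freq_table")
}

#' @export
print.freq_table <- function(x, ...) {
  cat("Allele frequencies -", x$population, "\n")
  for (a in names(x$arms)) {
    v <- x$arms[[a]]
    cat(" ", a, ":", paste(sprintf("%s=%.3f", names(v), v), collapse = " "), "\n")
  }
  invisible(x)
}

#' Banding-sequence (allele) frequencies of a population sample
#'
#' `p_i = f(ii) + sum_j f(ij)/2` per arm, computed on exact count arithmetic.
#'
#' @param sample a `population_sample`.
#' @return a `freq_table`.
#' @export
allele_frequencies <- function(sample) {
  stopifnot(inherits(sample, "population_sample"))
  cnt <- .sample_counts(sample)
  if (is.null(cnt) || nrow(cnt) == 0) stop("empty sample", call. = FALSE)
  arms <- lapply(split(cnt, cnt$arm), function(d) {
    d <- d[d$count > 0, , drop = FALSE]
    if (nrow(d) == 0) stop("arm with no observed genotypes", call. = FALSE)
    ids <- sort(unique(c(d$seq1, d$seq2)))
    w <- setNames(numeric(length(ids)), ids)
    for (i in seq_len(nrow(d))) {
      w[d$seq1[i]] <- w[d$seq1[i]] + d$count[i]
      w[d$seq2[i]] <- w[d$seq2[i]] + d$count[i]
    }
    w / (2 * sum(d$count))
  })
  allele_frequency_table(sample$code, arms)
}

# ---- polymorphism indices --------------------------------------------------

#' Polymorphism summary of a population
#'
#' Percentage of heterozygous larvae (at least one heterozygous arm), mean
#' number of heterozygous inversions per larva (each heterozygous arm counts
#' one), number of distinct banding sequences and genotypic combinations, and
#' B-chromosome carrier frequency. With aggregated counts instead of
#' larva-level data the per-larva heterozygosity is estimated assuming
#' independence between arms (flagged in the result).
#'
#' @param sample a `population_sample`.
#' @return object of class `polymorphism_summary`.
#' @export
polymorphism_summary <- function(sample) {
  stopifnot(inherits(sample, "population_sample"))
  cnt <- .sample_counts(sample)
  het <- cnt$seq1 != cnt$seq2
  harm <- vapply(split(data.frame(c = cnt$count, h = het), cnt$arm),
                 function(d) sum(d$c[d$h]) / sum(d$c), numeric(1))
  if (!is.null(sample$larvae)) {
    lv <- sample$larvae
    het_mat <- vapply(lv, function(col) {
      parts <- strsplit(col, "/", fixed = TRUE)
      vapply(parts, function(p) p[1] != p[2], logical(1))
    }, logical(nrow(lv)))
    if (is.null(dim(het_mat))) het_mat <- matrix(het_mat, nrow = 1)
    pct <- 100 * mean(rowSums(het_mat) > 0)
    hpl <- mean(rowSums(het_mat))
    exact <- TRUE
  } else {
    pct <- 100 * (1 - prod(1 - harm))
    hpl <- sum(harm)
    exact <- FALSE
  }
  ids <- unique(c(cnt$seq1[cnt$count > 0], cnt$seq2[cnt$count > 0]))
  gen <- unique(paste(cnt$arm, cnt$seq1, cnt$seq2)[cnt$count > 0])
  b <- sample$b_chromosomes
  b_freq <- if (length(b) > 1) mean(b > 0) else b / sample$n
  structure(list(population = sample$code,
                 pct_het_larvae = pct,
                 het_inv_per_larva = hpl,
                 n_sequences = length(ids),
                 n_genotypes = length(gen),
                 b_chromosome_freq = b_freq,
                 arm_het_freq = harm,
                 exact = exact),
            class = "polymorphism_summary")
}

#' @export
print.polymorphism_summary <- function(x, ...) {
  cat(sprintf("%s: %.1f%% heterozygous larvae, %.3f het. inversions/larva, %d sequences, %d genotypes\n",
              x$population, x$pct_het_larvae, x$het_inv_per_larva,
              x$n_sequences, x$n_genotypes))
  if (!x$exact) cat("  (per-larva indices assume independence between arms)\n")
  invisible(x)
}

#' Panel means of the quantitative polymorphism indices
#'
#' Unweighted arithmetic means of `pct_het_larvae` and `het_inv_per_larva`
#' across the populations admitted to quantitative analysis (the more-than-10
#' -specimens rule).
#'
#' @param summaries list of `polymorphism_summary` objects, or a data frame
#'   with columns `pct_het_larvae` and `het_inv_per_larva`.
#' @return named numeric vector with `pct_het_larvae` and
#'   `het_inv_per_larva` means and `n_populations`.
#' @export
quantitative_panel_means <- function(summaries) {
  if (is.data.frame(summaries)) {
    pct <- summaries$pct_het_larvae
    hpl <- summaries$het_inv_per_larva
  } else {
    if (length(summaries) == 0) stop("empty panel", call. = FALSE)
    pct <- vapply(summaries, `[[`, numeric(1), "pct_het_larvae")
    hpl <- vapply(summaries, `[[`, numeric(1), "het_inv_per_larva")
  }
  if (length(pct) == 0) stop("empty panel", call. = FALSE)
  c(pct_het_larvae = mean(pct), het_inv_per_larva = mean(hpl),
    n_populations = length(pct))
}

# ---- Hardy-Weinberg --------------------------------------------------------

#' Hardy-Weinberg expected genotype frequencies
#'
#' `E(ii) = p_i^2`, `E(ij) = 2 p_i p_j` for one arm's allele frequency
#' vector.
#'
#' @param freqs named numeric vector of allele frequencies (sum 1 within
#'   `tol`).
#' @param tol tolerance on the frequency sum.
#' @return named numeric vector over genotype classes `"i/j"`.
#' @export
hw_expected <- function(freqs, tol = 0.01) {
  if (any(freqs < 0)) stop("negative frequency", call. = FALSE)
  if (abs(sum(freqs) - 1) > tol) stop("frequencies do not sum to 1", call. = FALSE)
  ids <- names(freqs)
  if (is.null(ids)) ids <- as.character(seq_along(freqs))
  k <- length(freqs)
  out <- c()
  for (i in seq_len(k)) {
    for (j in i:k) {
      e <- if (i == j) freqs[i]^2 else 2 * freqs[i] * freqs[j]
      out[paste(ids[i], ids[j], sep = "/")] <- unname(e)
    }
  }
  out
}

.counts_to_geno_vec <- function(counts) {
  if (is.data.frame(counts)) {
    p <- .sort_pair(counts$seq1, counts$seq2)
    setNames(counts$count, paste(p$a, p$b, sep = "/"))
  } else counts
}

#' Chi-square test for Hardy-Weinberg proportions of one arm
#'
#' Alleles are inferred from the observed genotypes; expected counts follow
#' [hw_expected()] on the sample allele frequencies; classes expected and
#' observed zero are dropped. Degrees of freedom are
#' `k(k+1)/2 - k` for `k` alleles. The deviation direction is the sign of
#' (observed - expected) total heterozygote frequency.
#'
#' @param counts named numeric vector of genotype counts (names `"i/j"`), or
#'   a data frame with columns `seq1`, `seq2`, `count`.
#' @return object of class `hw_test`: observed/expected frequencies,
#'   `chi_square`, `df`, `p_value`, `direction`.
#' @export
hw_chi_square <- function(counts) {
  obs <- .counts_to_geno_vec(counts)
  n <- sum(obs)
  if (n < 1) stop("empty genotype counts", call. = FALSE)
  alleles <- unique(unlist(strsplit(names(obs), "/", fixed = TRUE)))
  p <- setNames(numeric(length(alleles)), alleles)
  for (g in names(obs)) {
    al <- strsplit(g, "/", fixed = TRUE)[[1]]
    p[al[1]] <- p[al[1]] + obs[g]
    p[al[2]] <- p[al[2]] + obs[g]
  }
  p <- p / (2 * n)
  e_freq <- hw_expected(p, tol = 1e-9)
  o_freq <- setNames(numeric(length(e_freq)), names(e_freq))
  for (g in names(obs)) {
    al <- strsplit(g, "/", fixed = TRUE)[[1]]
    key <- if (paste(al[1], al[2], sep = "/") %in% names(e_freq))
      paste(al[1], al[2], sep = "/") else paste(al[2], al[1], sep = "/")
    o_freq[key] <- o_freq[key] + obs[g]
  }
  o_freq <- o_freq / n
  keep <- !(e_freq == 0 & o_freq == 0)
  if (any(e_freq == 0 & o_freq > 0)) {
    stop("degenerate input: observed genotype with zero expected frequency",
         call. = FALSE)
  }
  k <- length(alleles)
  df <- k * (k + 1) / 2 - k
  if (df == 0) {
    chi <- 0; pv <- NA_real_; dir <- "none"
  } else {
    chi <- n * sum((o_freq[keep] - e_freq[keep])^2 / e_freq[keep])
    pv <- stats::pchisq(chi, df, lower.tail = FALSE)
    het <- grepl("/", names(e_freq)) &
      vapply(strsplit(names(e_freq), "/", fixed = TRUE),
             function(x) x[1] != x[2], logical(1))
    dobs <- sum(o_freq[het]) - sum(e_freq[het])
    dir <- if (dobs > 0) "het excess" else if (dobs < 0) "het deficit" else "none"
  }
  structure(list(n = n, alleles = p, observed = o_freq, expected = e_freq,
                 chi_square = chi, df = df, p_value = pv, direction = dir),
            class = "hw_test")
}

#' @export
print.hw_test <- function(x, ...) {
  cat(sprintf("HW chi-square: X2 = %.3f, df = %d, p = %s, %s (n = %d)\n",
              x$chi_square, x$df,
              if (is.na(x$p_value)) "NA (monomorphic)" else format.pval(x$p_value, digits = 3),
              x$direction, x$n))
  invisible(x)
}

#' Exact Hardy-Weinberg test by complete enumeration
#'
#' Enumerates every genotype array compatible with the observed allele
#' counts and sums the conditional probabilities (Levene's distribution) of
#' arrays no more probable than the observed one. Intended for small samples
#' (`n <= 50`) where the chi-square approximation is doubtful.
#'
#' @inheritParams hw_chi_square
#' @param max_n guard on the sample size (enumeration grows quickly).
#' @return list with `p_value`, `prob_observed`, `n_arrays`.
#' @export
hw_exact_test <- function(counts, max_n = 50) {
  obs <- .counts_to_geno_vec(counts)
  n <- sum(obs)
  if (n > max_n) stop("sample too large for complete enumeration", call. = FALSE)
  alleles <- sort(unique(unlist(strsplit(names(obs), "/", fixed = TRUE))))
  k <- length(alleles)
  if (k == 1) return(list(p_value = 1, prob_observed = 1, n_arrays = 1))
  cells <- t(utils::combn(seq_len(k), 2))
  cells <- rbind(cbind(seq_len(k), seq_len(k)), cells)  # homozygotes first
  obs_arr <- apply(cells, 1, function(ij) {
    g1 <- paste(alleles[ij[1]], alleles[ij[2]], sep = "/")
    g2 <- paste(alleles[ij[2]], alleles[ij[1]], sep = "/")
    sum(obs[names(obs) %in% c(g1, g2)])
  })
  allele_count <- setNames(numeric(k), alleles)
  for (r in seq_len(nrow(cells))) {
    allele_count[cells[r, 1]] <- allele_count[cells[r, 1]] + obs_arr[r]
    allele_count[cells[r, 2]] <- allele_count[cells[r, 2]] + obs_arr[r]
  }
  log_prob <- function(arr) {
    h <- sum(arr[cells[, 1] != cells[, 2]])
    lfactorial(n) - sum(lfactorial(arr)) + h * log(2) +
      sum(lfactorial(allele_count)) - lfactorial(2 * n)
  }
  lp_obs <- log_prob(obs_arr)
  probs <- c()
  recurse <- function(idx, remaining_n, remaining_alleles, arr) {
    if (idx == nrow(cells)) {
      last <- remaining_n
      ij <- cells[idx, ]
      need <- numeric(k); need[ij[1]] <- need[ij[1]] + last
      need[ij[2]] <- need[ij[2]] + last
      if (all(need == remaining_alleles)) {
        arr[idx] <- last
        probs[[length(probs) + 1]] <<- log_prob(arr)
      }
      return(invisible())
    }
    ij <- cells[idx, ]
    cap <- if (ij[1] == ij[2]) floor(min(remaining_alleles[ij[1]] / 2, remaining_n))
           else min(remaining_alleles[ij[1]], remaining_alleles[ij[2]], remaining_n)
    for (g in 0:cap) {
      ra <- remaining_alleles
      ra[ij[1]] <- ra[ij[1]] - g
      ra[ij[2]] <- ra[ij[2]] - g
      arr[idx] <- g
      recurse(idx + 1, remaining_n - g, ra, arr)
    }
  }
  recurse(1, n, allele_count, numeric(nrow(cells)))
  lps <- unlist(probs)
  pv <- sum(exp(lps[lps <= lp_obs + 1e-9]))
  list(p_value = min(pv, 1), prob_observed = exp(lp_obs), n_arrays = length(lps))
}

# ---- pool census -----------------------------------------------------------

#' Census of the banding-sequence pool
#'
#' @param tables list of `freq_table` objects (one per population).
#' @return list with `pool_size` (distinct sequences with nonzero frequency
#'   anywhere), `sequences`, and `per_population` counts.
#' @export
pool_census <- function(tables) {
  if (length(tables) < 1) stop("need at least one table", call. = FALSE)
  seqs_of <- function(t) {
    unlist(lapply(t$arms, function(v) names(v)[v > 0]), use.names = FALSE)
  }
  per_pop <- vapply(tables, function(t) length(seqs_of(t)), integer(1))
  names(per_pop) <- vapply(tables, `[[`, "", "population")
  all_ids <- sort(unique(unlist(lapply(tables, seqs_of))))
  list(pool_size = length(all_ids), sequences = all_ids,
       per_population = per_pop)
}
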