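# Synthetic data: population genotype samples under Hardy-Weinberg with an
# optional fixation-index deviation, and banding-sequence maps with planted
# reversals. Everything downstream (frequency estimation, HW testing,
# reversal-distance recovery) is testable against these generators without
# any external data.

#' Simulation configuration for a synthetic population
#'
#' Genotypes are drawn per arm with `P(ii) = p_i^2 + F p_i (1 - p_i)` and
#' `P(ij) = 2 p_i p_j (1 - F)`: `F = 0` is Hardy-Weinberg, negative `F`
#' gives heterozygote excess, positive `F` heterozygote deficit. Arms are
#' drawn independently (no inter-arm linkage is modelled).
#'
#' @param freqs named list (by arm letter) of named allele-frequency
#'   vectors, each summing to 1.
#' @param n number of larvae.
#' @param F fixation-index deviation in (-1, 1); must keep all genotype
#'   probabilities non-negative (`F >= -p_i/(1-p_i)` for every polymorphic
#'   allele).
#' @param b_prob per-larva probability of carrying a B chromosome.
#' @param seed integer seed; every draw from the configuration is
#'   reproducible given the seed.
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(freqs, n, F = 0, b_prob = 0, seed = 1) {
  stopifnot(is.list(freqs), length(freqs) > 0, n >= 1,
            F > -1, F < 1, b_prob >= 0, b_prob <= 1)
  for (a in names(freqs)) {
    p <- freqs[[a]]
    if (abs(sum(p) - 1) > 1e-9) stop("frequencies of arm ", a,
                                     " do not sum to 1", call. = FALSE)
    poly <- p[p > 0 & p < 1]
    if (length(poly) > 0 && F < max(-poly / (1 - poly))) {
      stop("infeasible F: genotype probabilities would be negative in arm ",
           a, call. = FALSE)
    }
  }
  structure(list(freqs = freqs, n = as.integer(n), F = F, b_prob = b_prob,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

.genotype_probs <- function(p, F) {
  ids <- names(p)
  k <- length(p)
  out <- c()
  for (i in seq_len(k)) {
    for (j in i:k) {
      pr <- if (i == j) p[i]^2 + F * p[i] * (1 - p[i])
            else 2 * p[i] * p[j] * (1 - F)
      out[paste(ids[i], ids[j], sep = "/")] <- unname(pr)
    }
  }
  out
}

#' Simulate a population sample
#'
#' Draws `n` larvae with independent per-arm genotypes under the
#' configuration's fixation-index model and Bernoulli B-chromosome carriage.
#'
#' @param cfg a [simulation_config()].
#' @param code population code for the sample.
#' @return a `population_sample` with larva-level data.
#' @export
simulate_population <- function(cfg, code = "SIM") {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(cfg$seed)
  larvae <- as.data.frame(lapply(cfg$freqs, function(p) {
    pr <- .genotype_probs(p, cfg$F)
    sample(names(pr), cfg$n, replace = TRUE, prob = pr)
  }), optional = TRUE)
  names(larvae) <- names(cfg$freqs)
  b <- stats::rbinom(cfg$n, 1, cfg$b_prob)
  population_sample(code, cfg$n, larvae = larvae, b_chromosomes = b,
                    meta = list(seed = cfg$seed, F = cfg$F))
}

# rebuild a sequence_map from an oriented band list by compressing maximal
# runs of canonically consecutive bands with consistent orientation
.bands_to_map <- function(bands, sign, cat, id) {
  uni <- cat$universe
  pos <- match(bands, uni)
  n <- length(pos)
  brk <- c(TRUE, vapply(2:n, function(j) {
    !(sign[j] != 0 && sign[j - 1] == sign[j] && pos[j] == pos[j - 1] + sign[j])
  }, logical(1)))
  run_id <- cumsum(brk)
  idinfo <- .parse_id(.norm_apostrophe(id))
  sec_of <- function(b) as.integer(sub("[a-z]$", "", b))
  let_of <- function(b) {
    l <- sub("^[0-9]+", "", b)
    if (l == "") NA_character_ else l
  }
  runs <- do.call(rbind, lapply(split(seq_len(n), run_id), function(idx) {
    b1 <- bands[idx[1]]; b2 <- bands[idx[length(idx)]]
    if (length(idx) == 1) {
      data.frame(s_sec = sec_of(b1), s_let = let_of(b1),
                 e_sec = sec_of(b1), e_let = let_of(b1),
                 direction = "singleton", fused = FALSE,
                 stringsAsFactors = FALSE)
    } else {
      dir <- if (sign[idx[1]] == 1) "ascending" else "descending"
      fuse <- length(idx) == 2 && sec_of(b1) == sec_of(b2) &&
        !is.na(let_of(b1))
      data.frame(s_sec = sec_of(b1), s_let = let_of(b1),
                 e_sec = sec_of(b2), e_let = let_of(b2),
                 direction = dir, fused = fuse, stringsAsFactors = FALSE)
    }
  }))
  rownames(runs) <- NULL
  structure(list(id = id, prefix = idinfo$prefix, tag = idinfo$tag,
                 arm = idinfo$arm, serial = idinfo$serial, runs = runs,
                 variant = NA_character_, unmapped = FALSE),
            class = "sequence_map")
}

#' Simulate a banding sequence derived by planted reversals
#'
#' Applies `k` uniformly random contiguous paracentric reversals (each of at
#' least two bands, so a reversal is never absorbed by the sign ambiguity of
#' a lone band) to the reference map's oriented band list and re-emits valid
#' notation. The planted scenario is returned for oracle use.
#'
#' @param reference a `sequence_map` to derive from.
#' @param k number of reversals (k >= 1).
#' @param seed integer seed.
#' @param cat optional `arm_catalogue`; inferred from the reference if
#'   `NULL`.
#' @param serial serial number for the derived map's id.
#' @return list with `map` (the derived `sequence_map`) and `scenario`
#'   (list of reversed band-index intervals in the reference traversal).
#' @export
simulate_derived_map <- function(reference, k, seed = 1, cat = NULL,
                                 serial = 90) {
  stopifnot(inherits(reference, "sequence_map"), k >= 1)
  if (is.null(cat)) cat <- infer_catalogue(list(reference))
  e <- expand_map(reference, cat)
  n <- nrow(e)
  if (n < 2) stop("degenerate reference: single band", call. = FALSE)
  bands <- e$band
  sign <- ifelse(e$sign == 0L, 1L, e$sign)  # resolve ambiguity arbitrarily
  set.seed(seed)
  scenario <- vector("list", k)
  for (r in seq_len(k)) {
    i <- sample.int(n - 1, 1)
    j <- sample(seq(i + 1, n), 1)
    bands[i:j] <- rev(bands[i:j])
    sign[i:j] <- -rev(sign[i:j])
    scenario[[r]] <- c(i, j)
  }
  id <- paste0(reference$prefix, reference$tag, reference$arm, serial)
  list(map = .bands_to_map(bands, sign, cat, id), scenario = scenario)
}
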