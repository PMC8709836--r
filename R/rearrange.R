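# Reversal distances between banding sequences of one arm.
#
# Two banding sequences related by paracentric inversions are a signed
# permutation of one another over the common segment refinement; the minimal
# number of contiguous-segment reversals transforming one into the other is
# found by iterative-deepening exhaustive search with a breakpoint-count
# bound. The centromere is terminal and never inside a reversal (all
# rearrangements handled here are paracentric), which is why plain linear
# signed permutations suffice.

#' Signed arrangement of one banding sequence relative to another
#'
#' Builds the [common_refinement()] of the pair and returns the target map as
#' a signed arrangement over the segment alphabet, the reference being the
#' identity `+1..+K`. Segments whose sign the notation leaves free (single
#' band runs) are flagged ambiguous.
#'
#' @param target,reference `sequence_map` objects of one arm.
#' @param cat optional `arm_catalogue`.
#' @return list with `perm` (signed integers), `ambiguous` (logical),
#'   `segments` (band content per segment id) and the ids involved.
#' @export
to_signed_arrangement <- function(target, reference, cat = NULL) {
  cr <- common_refinement(reference, target, cat)
  list(perm = cr$target, ambiguous = cr$ambiguous, segments = cr$segments,
       reference = cr$a_id, target = cr$b_id)
}

.breakpoints <- function(perm) {
  n <- length(perm)
  ext <- c(0L, perm, n + 1L)
  sum(ext[-1] - ext[-(n + 2)] != 1L)
}

.reverse_interval <- function(perm, i, j) {
  perm[i:j] <- -rev(perm[i:j])
  perm
}

.is_identity <- function(perm) all(perm == seq_along(perm))

# depth-limited DFS; reversals tried in lexicographic (i, j) order so the
# first witness found at the minimal depth is the lexicographically smallest
.dfs_reversals <- function(perm, remaining) {
  if (.is_identity(perm)) return(list())
  if (remaining == 0L) return(NULL)
  if (ceiling(.breakpoints(perm) / 2) > remaining) return(NULL)
  n <- length(perm)
  for (i in seq_len(n)) {
    for (j in i:n) {
      child <- .reverse_interval(perm, i, j)
      res <- .dfs_reversals(child, remaining - 1L)
      if (!is.null(res)) return(c(list(c(i, j)), res))
    }
  }
  NULL
}

.exact_distance <- function(perm, max_d) {
  for (d in 0:max_d) {
    res <- .dfs_reversals(perm, d)
    # the search sorts the target down to the identity; reversals are
    # positional involutions, so the reference-to-target scenario is the
    # same interval list in reverse order
    if (!is.null(res)) return(list(distance = d, scenario = rev(res)))
  }
  NULL
}

.ambiguous_assignments <- function(perm, ambiguous) {
  amb <- which(ambiguous)
  if (length(amb) == 0) return(list(perm))
  if (length(amb) > 12) {
    stop("too many ambiguous segments (", length(amb), ") to minimize over",
         call. = FALSE)
  }
  grid <- expand.grid(rep(list(c(1L, -1L)), length(amb)))
  lapply(seq_len(nrow(grid)), function(r) {
    p <- perm
    p[amb] <- abs(p[amb]) * unlist(grid[r, ])
    p
  })
}

#' Minimal reversal distance of a signed arrangement
#'
#' Exact minimal number of contiguous-segment reversals transforming the
#' identity reference into the target arrangement, minimized over all
#' assignments of ambiguous segment signs. Search is iterative deepening up
#' to `max_d` with breakpoint-count pruning; beyond `max_d` the breakpoint
#' lower bound is reported with `exact = FALSE`.
#'
#' @param arr a signed arrangement as returned by [to_signed_arrangement()],
#'   or a bare signed integer vector.
#' @param max_d maximum search depth (default 3; the packaged pool needs no
#'   more).
#' @return object of class `rearrangement_result`: list with `distance`,
#'   `exact`, `scenario` (list of reversed index intervals, `NULL` when not
#'   exact), `classification` (`identical`/`simple`/`complex`) and
#'   `n_segments`.
#' @export
reversal_distance <- function(arr, max_d = 3) {
  if (is.numeric(arr)) arr <- list(perm = as.integer(arr),
                                   ambiguous = rep(FALSE, length(arr)))
  stopifnot(is.list(arr), !is.null(arr$perm))
  if (is.null(arr$ambiguous)) arr$ambiguous <- rep(FALSE, length(arr$perm))
  if (!setequal(abs(arr$perm), seq_along(arr$perm))) {
    stop("arrangement is not a signed permutation of 1..n", call. = FALSE)
  }
  candidates <- .ambiguous_assignments(arr$perm, arr$ambiguous)
  best <- NULL
  for (p in candidates) {
    res <- .exact_distance(p, max_d)
    if (!is.null(res)) {
      better <- is.null(best) || res$distance < best$distance ||
        (res$distance == best$distance &&
           .scenario_lex_lt(res$scenario, best$scenario))
      if (better) best <- res
    }
  }
  if (is.null(best)) {
    lb <- min(vapply(candidates, function(p) ceiling(.breakpoints(p) / 2),
                     numeric(1)))
    out <- list(distance = max(lb, max_d + 1), exact = FALSE, scenario = NULL,
                n_segments = length(arr$perm))
  } else {
    out <- list(distance = best$distance, exact = TRUE,
                scenario = best$scenario, n_segments = length(arr$perm))
  }
  out$classification <- if (out$distance == 0) "identical"
    else if (out$distance == 1) "simple" else "complex"
  structure(c(out, arr[c("reference", "target")]),
            class = "rearrangement_result")
}

.scenario_lex_lt <- function(a, b) {
  fa <- unlist(a); fb <- unlist(b)
  for (i in seq_len(min(length(fa), length(fb)))) {
    if (fa[i] != fb[i]) return(fa[i] < fb[i])
  }
  length(fa) < length(fb)
}

#' Apply a reversal scenario to an arrangement
#'
#' @param perm signed integer vector (use the identity to replay a scenario
#'   from [reversal_distance()]).
#' @param scenario list of `c(i, j)` index intervals.
#' @return the transformed signed vector.
#' @export
apply_scenario <- function(perm, scenario) {
  for (rv in scenario) perm <- .reverse_interval(perm, rv[1], rv[2])
  perm
}

#' @export
print.rearrangement_result <- function(x, ...) {
  cat("Reversal distance:", x$distance,
      if (!x$exact) "(lower bound, search depth exceeded)" else "",
      "-", x$classification, "\n")
  if (!is.null(x$scenario) && length(x$scenario) > 0) {
    cat("Scenario (segment intervals):",
        paste(vapply(x$scenario, function(r) paste0("[", r[1], ",", r[2], "]"), ""),
              collapse = " "), "\n")
  }
  invisible(x)
}

#' Classify the relation between two banding sequences
#'
#' `identical` (reversal distance 0), `simple` (one inversion) or `complex`
#' (two or more inversions).
#'
#' @param a,b `sequence_map` objects of one arm.
#' @param cat optional `arm_catalogue`.
#' @param max_d search depth passed to [reversal_distance()].
#' @return character scalar.
#' @export
classify_pair <- function(a, b, cat = NULL, max_d = 3) {
  reversal_distance(to_signed_arrangement(b, a, cat), max_d)$classification
}

#' Band-coordinate breakpoints of a single inversion
#'
#' When two banding sequences differ by exactly one reversal, returns the
#' first and last band (in `a`'s traversal order) of the reversed block;
#' `NULL` otherwise.
#'
#' @param a,b `sequence_map` objects of one arm.
#' @param cat optional `arm_catalogue`.
#' @return named character vector `c(from=, to=)`, or `NULL` when the
#'   distance is not 1.
#' @export
single_reversal_breakpoints <- function(a, b, cat = NULL) {
  arr <- to_signed_arrangement(b, a, cat)
  res <- reversal_distance(arr)
  if (!res$exact || res$distance != 1) return(NULL)
  iv <- res$scenario[[1]]
  segs <- arr$segments
  c(from = segs[[iv[1]]][1], to = segs[[iv[2]]][length(segs[[iv[2]]])])
}

#' Compare two sequences of a pool
#'
#' Convenience wrapper: resolves ids in a [read_pool()] object, computes the
#' signed arrangement, reversal distance, classification and (for simple
#' inversions) the inverted band interval.
#'
#' @param pool a `band_pool`.
#' @param id_a,id_b sequence ids (full or arm+serial short form).
#' @param max_d search depth.
#' @return a `rearrangement_result` with an added `breakpoints` field.
#' @export
pool_compare <- function(pool, id_a, id_b, max_d = 3) {
  a <- pool_sequence(pool, id_a)
  b <- pool_sequence(pool, id_b)
  cat <- pool$catalogues[[a$arm]]
  arr <- to_signed_arrangement(b, a, cat)
  res <- reversal_distance(arr, max_d)
  res$breakpoints <- if (res$exact && res$distance == 1)
    single_reversal_breakpoints(a, b, cat) else NULL
  res
}
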