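# Cytogenetic structure typing of populations.
#
# A population is type "0" when the main (serial-1) banding sequence holds a
# strict majority (> 0.5) in every arm; otherwise the type label collects,
# alphabetically, the letters of arms where an alternative sequence is
# dominant. Arms with no strict majority are flagged mixed and excluded from
# the label.

.seq_serial <- function(id) as.integer(sub("^.*[A-G]", "", id))
.seq_arm <- function(id) sub("^.*?([A-G])[0-9]+$", "\\1", id)

#' Classify a population's cytogenetic structure type
#'
#' @param t a `freq_table` covering all seven arms A-G.
#' @return object of class `structure_type`: `label` (`"0"` or sorted arm
#'   letters), `dominant` (dominant sequence id per arm), `mixed` (arms with
#'   no strict majority).
#' @export
classify_structure <- function(t) {
  stopifnot(inherits(t, "freq_table"))
  need <- LETTERS[1:7]
  miss <- setdiff(need, names(t$arms))
  if (length(miss) > 0) stop("missing arm(s): ", paste(miss, collapse = ", "),
                             call. = FALSE)
  dominant <- character(0)
  mixed <- character(0)
  alt <- character(0)
  for (a in need) {
    v <- t$arms[[a]]
    w <- which(v > 0.5)
    if (length(w) == 0) {
      mixed <- c(mixed, a)
      dominant[a] <- NA_character_
    } else {
      id <- names(v)[w]
      dominant[a] <- id
      if (.seq_serial(id) != 1) alt <- c(alt, a)
    }
  }
  label <- if (length(alt) == 0) "0" else paste(sort(unique(alt)), collapse = "")
  structure(list(population = t$population, label = label,
                 dominant = dominant, mixed = mixed),
            class = "structure_type")
}

#' @export
print.structure_type <- function(x, ...) {
  cat(sprintf("%s: cytogenetic type %s%s\n", x$population, x$label,
              if (length(x$mixed)) paste0(" (mixed arms: ",
                                          paste(x$mixed, collapse = ","), ")") else ""))
  invisible(x)
}

#' Frequency-polygon vector of the main banding sequences
#'
#' Ordered vector of the serial-1 sequence's frequency per arm A-G, the raw
#' material of the published frequency polygons.
#'
#' @param t a `freq_table` covering arms A-G.
#' @return named numeric vector of length 7.
#' @export
polygon_vectors <- function(t) {
  stopifnot(inherits(t, "freq_table"))
  need <- LETTERS[1:7]
  miss <- setdiff(need, names(t$arms))
  if (length(miss) > 0) stop("missing arm(s): ", paste(miss, collapse = ", "),
                             call. = FALSE)
  vapply(need, function(a) {
    v <- t$arms[[a]]
    main <- which(.seq_serial(names(v)) == 1)
    if (length(main) == 0) 0 else unname(v[main[1]])
  }, numeric(1))
}
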