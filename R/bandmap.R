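# Banding-sequence map notation: parsing, catalogues, expansion, validation,
# refinement and formatting.
#
# A banding sequence is written as an id token, a series of band-run tokens and
# a terminal centromere marker "C", e.g.
#   p'agiB1 25s-q 18n-16a 22a-r 25k-23f 15g-r 21t-i 18o-21h 25p-l 22s-23e 15f-12v C
# Band coordinates are section numbers with optional lowercase letter
# subdivisions; runs are ranges ("22a-r", "18n-16a"), fused two-letter pairs
# ("22ab") or single bands ("3i").

LETTERS_LC <- letters

.norm_apostrophe <- function(x) gsub("’", "'", x)

.letter_idx <- function(l) ifelse(is.na(l) | l == "", 0L, match(l, LETTERS_LC))

.band_name <- function(section, letter) {
  paste0(section, ifelse(is.na(letter), "", letter))
}

.band_key <- function(section, letter) {
  section * 100L + .letter_idx(letter)
}

# ---- parsing ---------------------------------------------------------------

.parse_id <- function(tok) {
  # prefix letter marks geographic distribution (p' Palearctic, h' Holarctic,
  # and so on); any single lowercase marker is accepted
  m <- regmatches(tok, regexec("^([a-z])'([a-z]{2,4})([A-G])([0-9]+)$", tok))[[1]]
  if (length(m) == 0) {
    stop("malformed sequence id token: '", tok, "'", call. = FALSE)
  }
  list(prefix = paste0(m[2], "'"), tag = m[3], arm = m[4],
       serial = as.integer(m[5]))
}

.parse_run_token <- function(tok) {
  m <- regmatches(tok, regexec("^([0-9]+)([a-z]*)(-([0-9]*)([a-z]*))?$", tok))[[1]]
  if (length(m) == 0 || (m[4] != "" && m[5] == "" && m[6] == "")) {
    stop("malformed band run token: '", tok, "'", call. = FALSE)
  }
  s_sec <- as.integer(m[2])
  s_let <- m[3]
  hyphen <- m[4] != ""
  if (!hyphen) {
    if (nchar(s_let) == 2) {
      # fused two-letter run, e.g. "22ab" or "6hg"; letters must be adjacent
      l1 <- substr(s_let, 1, 1)
      l2 <- substr(s_let, 2, 2)
      if (abs(.letter_idx(l1) - .letter_idx(l2)) != 1) {
        stop("fused token with non-adjacent letters: '", tok, "'", call. = FALSE)
      }
      dir <- if (.letter_idx(l1) < .letter_idx(l2)) "ascending" else "descending"
      return(data.frame(s_sec = s_sec, s_let = l1, e_sec = s_sec, e_let = l2,
                        direction = dir, fused = TRUE,
                        stringsAsFactors = FALSE))
    }
    if (nchar(s_let) > 2) {
      stop("malformed band run token: '", tok, "'", call. = FALSE)
    }
    return(data.frame(s_sec = s_sec, s_let = if (s_let == "") NA_character_ else s_let,
                      e_sec = s_sec, e_let = if (s_let == "") NA_character_ else s_let,
                      direction = "singleton", fused = FALSE,
                      stringsAsFactors = FALSE))
  }
  if (nchar(s_let) > 1 || nchar(m[6]) > 1) {
    stop("malformed band run token: '", tok, "'", call. = FALSE)
  }
  e_sec <- if (m[5] == "") s_sec else as.integer(m[5])
  e_let <- if (m[6] == "") NA_character_ else m[6]
  s_let <- if (s_let == "") NA_character_ else s_let
  k1 <- .band_key(s_sec, s_let)
  k2 <- .band_key(e_sec, e_let)
  dir <- if (k1 < k2) "ascending" else if (k1 > k2) "descending" else "singleton"
  data.frame(s_sec = s_sec, s_let = s_let, e_sec = e_sec, e_let = e_let,
             direction = dir, fused = FALSE, stringsAsFactors = FALSE)
}

#' Parse one banding-sequence listing line
#'
#' Parses a line of the cytogenetic listing notation (id token, band runs,
#' terminal centromere marker `C`, optional trailing mapping-version tag such
#' as `(GV)`) into a `sequence_map` object.
#'
#' @param text a single listing line, e.g.
#'   `"p'agiF1 1a-d 6e-1e 7a-10d 18c-a 11a-17d 18d-23f C"`. Both ASCII and
#'   typographic apostrophes are accepted in the id.
#' @return an object of class `sequence_map` with fields `id`, `prefix`,
#'   `tag`, `arm`, `serial`, `runs` (a data frame of oriented band runs),
#'   and `variant` (`NA`, or a mapping-version tag like `"GV"`).
#' @examples
#' m <- parse_sequence_line("p'agiF1 1a-d 6e-1e 7a-10d 18c-a 11a-17d 18d-23f C")
#' m$arm
#' nrow(m$runs)
#' @export
parse_sequence_line <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  text <- trimws(.norm_apostrophe(text))
  if (text == "") stop("empty sequence line", call. = FALSE)
  variant <- NA_character_
  vm <- regmatches(text, regexec("\\(([A-Z]{1,3})\\)$", text))[[1]]
  if (length(vm) > 0) {
    variant <- vm[2]
    text <- trimws(sub("\\([A-Z]{1,3}\\)$", "", text))
  }
  toks <- strsplit(text, "[[:space:]]+")[[1]]
  if (length(toks) == 2 && toks[2] == "unmapped") {
    # placeholder for an arm whose banding pattern has no published map
    idinfo <- .parse_id(toks[1])
    return(structure(
      list(id = toks[1], prefix = idinfo$prefix, tag = idinfo$tag,
           arm = idinfo$arm, serial = idinfo$serial,
           runs = .parse_run_token("1a")[0, ], variant = variant,
           unmapped = TRUE),
      class = "sequence_map"))
  }
  if (length(toks) < 3) {
    stop("sequence line needs an id, at least one run and a terminal 'C': '",
         text, "'", call. = FALSE)
  }
  idinfo <- .parse_id(toks[1])
  if (toks[length(toks)] != "C") {
    stop("missing terminal centromere marker 'C' in '", text, "'", call. = FALSE)
  }
  run_toks <- toks[-c(1, length(toks))]
  if ("C" %in% run_toks) {
    stop("centromere marker 'C' must be terminal and unique", call. = FALSE)
  }
  runs <- do.call(rbind, lapply(run_toks, .parse_run_token))
  structure(
    list(id = toks[1], prefix = idinfo$prefix, tag = idinfo$tag,
         arm = idinfo$arm, serial = idinfo$serial, runs = runs,
         variant = variant, unmapped = FALSE),
    class = "sequence_map")
}

#' @export
print.sequence_map <- function(x, ...) {
  cat(format_sequence_line(x), "\n")
  invisible(x)
}

# ---- catalogue -------------------------------------------------------------

.endpoint_table <- function(maps) {
  do.call(rbind, lapply(maps, function(m) {
    r <- m$runs
    data.frame(sec = c(r$s_sec, r$e_sec), let = c(r$s_let, r$e_let),
               stringsAsFactors = FALSE)
  }))
}

#' Infer the band catalogue of a chromosome arm
#'
#' The band universe of an arm is implicit in its listings: per section the
#' lettered subdivisions are assumed contiguous from `a` to the highest letter
#' observed in any token, and sections only ever covered inside cross-section
#' ranges (never split by a run endpoint) are treated as atomic single bands.
#' The catalogue records the bands actually covered by the supplied maps, in
#' canonical (physical) order.
#'
#' @param maps a list of `sequence_map` objects of one arm (one mapping
#'   version; mapping versions such as KV/GV must not be mixed).
#' @return an object of class `arm_catalogue` with fields `arm`, `bands`
#'   (character vector in canonical order), `letter_count` (named integer,
#'   0 for atomic sections) and `universe` (all bands implied by the
#'   contiguity assumption).
#' @examples
#' m <- parse_sequence_line("x'tstA1 1a-3c C")
#' infer_catalogue(list(m))$bands
#' @export
infer_catalogue <- function(maps) {
  if (is.null(maps) || length(maps) < 1) stop("need at least one map", call. = FALSE)
  arms <- unique(vapply(maps, `[[`, "", "arm"))
  if (length(arms) != 1) stop("maps belong to different arms: ",
                              paste(arms, collapse = ", "), call. = FALSE)
  ep <- .endpoint_table(maps)
  lettered <- tapply(.letter_idx(ep$let), ep$sec, max)
  secs_lettered <- as.integer(names(lettered))[lettered > 0]
  secs_bare <- unique(ep$sec[is.na(ep$let)])
  conflict <- intersect(secs_lettered, secs_bare)
  if (length(conflict) > 0) {
    stop("catalogue conflict: section(s) ", paste(conflict, collapse = ", "),
         " referenced both as atomic and as lettered", call. = FALSE)
  }
  # sections interior to a cross-section range are atomic unless lettered
  interior <- unlist(lapply(maps, function(m) {
    r <- m$runs
    unlist(Map(function(a, b) if (abs(b - a) > 1) seq(min(a, b) + 1L, max(a, b) - 1L)
               else integer(0), r$s_sec, r$e_sec))
  }))
  all_secs <- sort(unique(c(ep$sec, interior)))
  letter_count <- vapply(all_secs, function(s) {
    i <- match(as.character(s), names(lettered))
    if (!is.na(i)) as.integer(lettered[i]) else 0L
  }, integer(1))
  names(letter_count) <- all_secs
  universe <- do.call(rbind, lapply(seq_along(all_secs), function(i) {
    s <- all_secs[i]; k <- letter_count[i]
    if (k == 0) data.frame(sec = s, let = NA_character_, stringsAsFactors = FALSE)
    else data.frame(sec = s, let = LETTERS_LC[seq_len(k)], stringsAsFactors = FALSE)
  }))
  universe$name <- .band_name(universe$sec, universe$let)
  cat0 <- structure(list(arm = arms, letter_count = letter_count,
                         universe = universe$name, bands = universe$name),
                    class = "arm_catalogue")
  covered <- unique(unlist(lapply(maps, function(m) expand_map(m, cat0)$band)))
  cat0$bands <- universe$name[universe$name %in% covered]
  cat0
}

#' @export
print.arm_catalogue <- function(x, ...) {
  cat("Arm", x$arm, "catalogue:", length(x$bands), "bands in",
      length(x$letter_count), "sections\n")
  invisible(x)
}

# ---- expansion -------------------------------------------------------------

.claimed_bands <- function(map) {
  r <- map$runs
  cl <- r[r$fused | r$direction == "singleton", , drop = FALSE]
  unique(c(.band_name(cl$s_sec, cl$s_let), .band_name(cl$e_sec, cl$e_let)))
}

#' Expand a banding-sequence map to an oriented band list
#'
#' Expands every run to the bands it covers, emitted in traversal (listing)
#' order. Range runs expand to the canonical-order interval between their
#' endpoints; bands explicitly claimed by a singleton or fused token of the
#' same map take precedence and are excluded from the interpolated interior
#' of range runs. Bands inside descending runs are oriented `-1`, ascending
#' `+1`; single-band runs carry orientation `0` (ambiguous: the notation
#' cannot express a lone band's orientation).
#'
#' @param map a `sequence_map`.
#' @param cat an `arm_catalogue` covering every referenced band.
#' @return a data frame with columns `band` and `sign` in traversal order.
#' @export
expand_map <- function(map, cat) {
  stopifnot(inherits(map, "sequence_map"), inherits(cat, "arm_catalogue"))
  uni <- cat$universe
  claimed <- .claimed_bands(map)
  out <- vector("list", nrow(map$runs))
  for (i in seq_len(nrow(map$runs))) {
    r <- map$runs[i, ]
    b1 <- .band_name(r$s_sec, r$s_let)
    b2 <- .band_name(r$e_sec, r$e_let)
    p1 <- match(b1, uni); p2 <- match(b2, uni)
    if (is.na(p1) || is.na(p2)) {
      stop("run endpoint not in catalogue: ",
           paste(c(b1, b2)[is.na(c(p1, p2))], collapse = ", "), call. = FALSE)
    }
    if (r$direction == "singleton") {
      out[[i]] <- data.frame(band = b1, sign = 0L, run = i,
                             stringsAsFactors = FALSE)
    } else if (r$fused) {
      sgn <- if (r$direction == "ascending") 1L else -1L
      out[[i]] <- data.frame(band = c(b1, b2), sign = sgn, run = i,
                             stringsAsFactors = FALSE)
    } else {
      lo <- min(p1, p2); hi <- max(p1, p2)
      members <- uni[lo:hi]
      members <- members[!(members %in% setdiff(claimed, c(b1, b2)))]
      if (r$direction == "descending") {
        members <- rev(members); sgn <- -1L
      } else sgn <- 1L
      out[[i]] <- data.frame(band = members, sign = sgn, run = i,
                             stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

# ---- validation ------------------------------------------------------------

#' Validate that the banding sequences of one arm share one band set
#'
#' All banding sequences of an arm must be permutations of one underlying
#' band set (inversions rearrange bands, they do not create or destroy them).
#' The report lists missing, extra, and duplicated bands per map.
#'
#' @param maps list of `sequence_map` objects of one arm.
#' @param cat optional `arm_catalogue`; inferred from `maps` when `NULL`.
#' @return an object of class `arm_validation`: list with `ok` (logical),
#'   `arm`, `catalogue`, and `per_map` details.
#' @export
validate_arm_pool <- function(maps, cat = NULL) {
  if (length(maps) < 1) stop("need at least one map", call. = FALSE)
  if (is.null(cat)) cat <- infer_catalogue(maps)
  ref <- sort(cat$bands)
  per_map <- lapply(maps, function(m) {
    got <- expand_map(m, cat)$band
    dup <- unique(got[duplicated(got)])
    list(id = m$id,
         missing = setdiff(ref, got),
         extra = setdiff(unique(got), ref),
         duplicated = dup,
         n = length(got))
  })
  names(per_map) <- vapply(maps, `[[`, "", "id")
  ok <- all(vapply(per_map, function(p) {
    length(p$missing) == 0 && length(p$extra) == 0 &&
      length(p$duplicated) == 0 && p$n == length(ref)
  }, logical(1)))
  structure(list(ok = ok, arm = cat$arm, catalogue = cat, per_map = per_map),
            class = "arm_validation")
}

#' @export
print.arm_validation <- function(x, ...) {
  cat("Arm", x$arm, "pool validation:", if (x$ok) "PASS" else "FAIL", "\n")
  for (p in x$per_map) {
    if (length(p$missing) || length(p$extra) || length(p$duplicated)) {
      cat("  ", p$id, ": missing [", paste(p$missing, collapse = " "),
          "] extra [", paste(p$extra, collapse = " "),
          "] duplicated [", paste(p$duplicated, collapse = " "), "]\n")
    }
  }
  invisible(x)
}

# ---- common refinement -----------------------------------------------------

#' Common segment refinement of two banding sequences
#'
#' Renders two banding sequences of one arm over a shared alphabet of
#' segments: maximal blocks of bands that are contiguous, in the same
#' relative orientation, in both maps. Map `a` becomes the identity
#' arrangement `1..K` (all `+`); map `b` becomes a signed arrangement of the
#' same segment ids. Segments arising from single-band runs carry a free
#' (ambiguous) sign.
#'
#' @param a,b `sequence_map` objects of one arm (same mapping version).
#' @param cat optional `arm_catalogue`; inferred from `list(a, b)` if `NULL`.
#' @return a list with `n_segments`, `segments` (bands per segment, in `a`'s
#'   traversal order), `ref` (identity), `target` (signed integer vector),
#'   `ambiguous` (logical mask) and the two ids.
#' @export
common_refinement <- function(a, b, cat = NULL) {
  stopifnot(inherits(a, "sequence_map"), inherits(b, "sequence_map"))
  if (a$arm != b$arm) stop("maps belong to different arms", call. = FALSE)
  if (is.null(cat)) cat <- infer_catalogue(list(a, b))
  v <- validate_arm_pool(list(a, b), cat)
  if (!v$ok) stop("arm pool validation failed for ", a$id, " / ", b$id,
                  "; refinement undefined", call. = FALSE)
  ea <- expand_map(a, cat)
  eb <- expand_map(b, cat)
  n <- nrow(ea)
  posb <- match(ea$band, eb$band)
  # relative orientation of each band: product of the run orientations in the
  # two maps; 0 (free) when either side is a single-band run
  rel <- ifelse(ea$sign == 0L | eb$sign[posb] == 0L, 0L,
                ea$sign * eb$sign[posb])
  # a segment boundary falls wherever a run boundary of either map falls:
  # two a-consecutive bands stay in one segment only if they share a run in
  # both maps and sit adjacent in b with consistent orientation
  brk <- c(TRUE, vapply(2:n, function(p) {
    !(ea$run[p] == ea$run[p - 1] &&
        eb$run[posb[p]] == eb$run[posb[p - 1]] &&
        rel[p] != 0L && rel[p] == rel[p - 1] &&
        posb[p] - posb[p - 1] == rel[p])
  }, logical(1)))
  seg_id <- cumsum(brk)             # segments numbered along a = identity
  K <- seg_id[n]
  seg_idx <- split(seq_len(n), seg_id)
  segments <- lapply(seg_idx, function(idx) ea$band[idx])
  seg_rel <- vapply(seg_idx, function(idx) rel[idx[1]], integer(1))
  seg_b_start <- vapply(seg_idx, function(idx) min(posb[idx]), integer(1))
  b_ord <- order(seg_b_start)       # segments in b-traversal order
  target <- integer(K); ambiguous <- logical(K)
  for (j in seq_len(K)) {
    s <- b_ord[j]
    target[j] <- if (seg_rel[s] == -1L) -s else s
    ambiguous[j] <- seg_rel[s] == 0L
  }
  list(n_segments = K, segments = unname(segments), ref = seq_len(K),
       target = target, ambiguous = ambiguous, a_id = a$id, b_id = b$id)
}

# ---- formatting ------------------------------------------------------------

.format_run <- function(r) {
  if (r$direction == "singleton") return(.band_name(r$s_sec, r$s_let))
  if (r$fused) return(paste0(r$s_sec, r$s_let, r$e_let))
  if (r$s_sec == r$e_sec) {
    paste0(r$s_sec, r$s_let, "-", r$e_let)
  } else {
    paste0(.band_name(r$s_sec, r$s_let), "-", .band_name(r$e_sec, r$e_let))
  }
}

#' Render a banding-sequence map back to its listing line
#'
#' Inverse of [parse_sequence_line()]: `parse_sequence_line(format_sequence_line(m))`
#' reproduces `m`. Fused two-letter runs re-emit fused (`"22ab"`), as in the
#' source dialect.
#'
#' @param map a `sequence_map`.
#' @return a single listing line.
#' @export
format_sequence_line <- function(map) {
  stopifnot(inherits(map, "sequence_map"))
  if (isTRUE(map$unmapped)) return(paste(map$id, "unmapped"))
  toks <- vapply(seq_len(nrow(map$runs)),
                 function(i) .format_run(map$runs[i, ]), "")
  line <- paste(c(map$id, toks, "C"), collapse = " ")
  if (!is.na(map$variant)) line <- paste0(line, " (", map$variant, ")")
  line
}

#' Test two sequence maps for equality
#'
#' Maps are equal when id, arm, mapping version and the full oriented run
#' lists coincide.
#' @param a,b `sequence_map` objects.
#' @return logical.
#' @export
sequence_maps_equal <- function(a, b) {
  identical(a$id, b$id) && identical(a$arm, b$arm) &&
    identical(is.na(a$variant), is.na(b$variant)) &&
    (is.na(a$variant) || identical(a$variant, b$variant)) &&
    isTRUE(all.equal(a$runs, b$runs, check.attributes = FALSE))
}

# ---- pool files ------------------------------------------------------------

#' Read a banding-sequence pool file
#'
#' A pool file is UTF-8 text with one listing line per sequence and `#`
#' comments; a comment of the form `# arms: A B C D E F G` may declare the
#' arm inventory. Alternative mapping versions of one sequence (trailing
#' `(KV)`/`(GV)` tags) are kept apart: the GV version is the packaged default
#' and other versions are stored as alternates, never mixed with the default
#' in one catalogue.
#'
#' @param path path to the pool file.
#' @return an object of class `band_pool`: list with `maps` (named by id),
#'   `alternates`, `arms`, and per-arm `catalogues`.
#' @export
read_pool <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- .norm_apostrophe(lines)
  arms_decl <- NULL
  hdr <- grep("^#.*arms:", lines, value = TRUE)
  if (length(hdr) > 0) {
    arms_decl <- strsplit(trimws(sub(".*arms:", "", hdr[1])), "[[:space:]]+")[[1]]
  }
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[lines != ""]
  parsed <- lapply(lines, parse_sequence_line)
  ids <- vapply(parsed, `[[`, "", "id")
  variants <- vapply(parsed, `[[`, "", "variant")
  default <- list(); alternates <- list()
  for (i in seq_along(parsed)) {
    m <- parsed[[i]]
    is_default <- is.na(m$variant) || m$variant == "GV" ||
      sum(ids == m$id) == 1
    if (is_default && is.null(default[[m$id]])) {
      default[[m$id]] <- m
    } else if (is_default) {
      stop("duplicate sequence id in pool: ", m$id, call. = FALSE)
    } else {
      alternates[[m$id]] <- c(alternates[[m$id]], list(m))
    }
  }
  mapped <- Filter(function(m) !isTRUE(m$unmapped), default)
  arms <- sort(unique(vapply(mapped, `[[`, "", "arm")))
  catalogues <- lapply(arms, function(a) {
    infer_catalogue(Filter(function(m) m$arm == a, mapped))
  })
  names(catalogues) <- arms
  structure(list(maps = default, alternates = alternates,
                 arms = if (is.null(arms_decl)) arms else arms_decl,
                 catalogues = catalogues, path = path),
            class = "band_pool")
}

#' @export
print.band_pool <- function(x, ...) {
  cat("Banding-sequence pool:", length(x$maps), "sequences, arms",
      paste(names(x$catalogues), collapse = ""), "\n")
  invisible(x)
}

#' Look up a sequence in a pool
#'
#' Accepts a full id (`"p'agiB2"`), or the arm+serial short form (`"B2"`).
#'
#' @param pool a `band_pool`.
#' @param id full or short sequence id.
#' @param variant optional mapping-version tag to fetch an alternate (e.g.
#'   `"KV"`).
#' @return a `sequence_map`.
#' @export
pool_sequence <- function(pool, id, variant = NULL) {
  stopifnot(inherits(pool, "band_pool"))
  id <- .norm_apostrophe(id)
  hit <- NULL
  if (id %in% names(pool$maps)) {
    hit <- pool$maps[[id]]
  } else if (grepl("^[A-G][0-9]+$", id)) {
    short <- vapply(pool$maps, function(m) paste0(m$arm, m$serial), "")
    w <- which(short == id)
    if (length(w) == 1) hit <- pool$maps[[w]]
  }
  if (is.null(hit)) stop("sequence not found in pool: ", id, call. = FALSE)
  if (!is.null(variant)) {
    alts <- pool$alternates[[hit$id]]
    for (a in alts) if (identical(a$variant, variant)) return(a)
    if (!identical(hit$variant, variant)) {
      stop("no version '", variant, "' of ", hit$id, " in pool", call. = FALSE)
    }
  }
  hit
}

#' All default-version sequences of one arm
#' @param pool a `band_pool`.
#' @param arm arm letter.
#' @return list of `sequence_map` objects.
#' @export
pool_arm <- function(pool, arm) {
  out <- Filter(function(m) m$arm == arm, pool$maps)
  if (length(out) == 0) stop("no sequences for arm ", arm, call. = FALSE)
  out
}
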