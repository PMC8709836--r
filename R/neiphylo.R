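# Nei (1972) standard genetic identity/distance between populations over the
# chromosome-arm loci, distance matrices, and neighbor-joining trees.
#
# The J terms are averaged across loci BEFORE forming the identity
# I = J_XY / sqrt(J_X * J_Y); this "standard" variant (not a per-locus mean
# of identities) is the one that reproduces the published distance matrix.
# All seven arms enter the mean: a shared monomorphic arm contributes 1 to
# every J and so dilutes the distance, which is intended.

#' Nei (1972) standard identity and distance between two populations
#'
#' @param x,y `freq_table` objects.
#' @param loci arm letters to use (default: the union of arms present, which
#'   for the packaged tables is A-G). Every listed locus must be present in
#'   both tables; absent alleles count as frequency 0.
#' @return object of class `nei_result`: `J_X`, `J_Y`, `J_XY`, `I`
#'   (clamped to at most 1 so rounding noise cannot give negative
#'   distances), `D = -log(I)`.
#' @export
nei_distance <- function(x, y, loci = NULL) {
  stopifnot(inherits(x, "freq_table"), inherits(y, "freq_table"))
  if (is.null(loci)) loci <- sort(union(names(x$arms), names(y$arms)))
  if (length(loci) == 0) stop("empty locus list", call. = FALSE)
  miss <- setdiff(loci, intersect(names(x$arms), names(y$arms)))
  if (length(miss) > 0) {
    stop("locus missing from a table: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  jx <- jy <- jxy <- numeric(length(loci))
  for (i in seq_along(loci)) {
    xv <- x$arms[[loci[i]]]
    yv <- y$arms[[loci[i]]]
    ids <- union(names(xv), names(yv))
    xa <- setNames(numeric(length(ids)), ids); xa[names(xv)] <- xv
    ya <- setNames(numeric(length(ids)), ids); ya[names(yv)] <- yv
    jx[i] <- sum(xa^2)
    jy[i] <- sum(ya^2)
    jxy[i] <- sum(xa * ya)
  }
  J_X <- mean(jx); J_Y <- mean(jy); J_XY <- mean(jxy)
  I <- min(J_XY / sqrt(J_X * J_Y), 1)
  structure(list(J_X = J_X, J_Y = J_Y, J_XY = J_XY, I = I, D = -log(I),
                 x = x$population, y = y$population, loci = loci),
            class = "nei_result")
}

#' @export
print.nei_result <- function(x, ...) {
  cat(sprintf("Nei (1972) %s vs %s: I = %.4f, D = %.4f\n",
              x$x, x$y, x$I, x$D))
  invisible(x)
}

#' Pairwise Nei distance matrix
#'
#' @param tables list of `freq_table` objects with distinct population codes.
#' @param loci passed to [nei_distance()].
#' @return symmetric numeric matrix (class `nei_dist_matrix`) with zero
#'   diagonal, labelled by population code.
#' @export
distance_matrix <- function(tables, loci = NULL) {
  if (length(tables) < 2) stop("need at least two tables", call. = FALSE)
  codes <- vapply(tables, `[[`, "", "population")
  if (anyDuplicated(codes)) stop("duplicate population codes", call. = FALSE)
  k <- length(tables)
  m <- matrix(0, k, k, dimnames = list(codes, codes))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      d <- nei_distance(tables[[i]], tables[[j]], loci)$D
      m[i, j] <- m[j, i] <- d
    }
  }
  class(m) <- c("nei_dist_matrix", class(m))
  m
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration (via [ape::nj()]); negative branch lengths are
#' clamped to zero.
#'
#' @param m symmetric non-negative distance matrix with labels (a plain
#'   matrix or `nei_dist_matrix`).
#' @return an [ape::phylo] tree over the matrix labels.
#' @export
nj_tree <- function(m) {
  m <- unclass(m)
  if (!is.matrix(m) || nrow(m) != ncol(m)) stop("need a square matrix", call. = FALSE)
  if (nrow(m) < 3) stop("neighbor-joining needs at least 3 leaves", call. = FALSE)
  if (max(abs(m - t(m))) > 1e-8) stop("matrix is not symmetric", call. = FALSE)
  if (any(m < 0)) stop("negative distances", call. = FALSE)
  tr <- ape::nj(m)
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Write / read trees in Newick format
#'
#' Thin wrappers over [ape::write.tree()] / [ape::read.tree()] so tree
#' serialization round-trips topology and branch lengths.
#'
#' @param tree an `ape::phylo` object.
#' @param path file path (or `NULL` to return the Newick string).
#' @return `write_newick`: the Newick string, invisibly when written to a
#'   file; `read_newick`: a `phylo`.
#' @export
write_newick <- function(tree, path = NULL) {
  s <- ape::write.tree(tree)
  if (!is.null(path)) {
    writeLines(s, path)
    return(invisible(s))
  }
  s
}

#' @rdname write_newick
#' @export
read_newick <- function(path) {
  ape::read.tree(path)
}

#' Read a labelled distance matrix
#'
#' Accepts the published lower-triangle-with-labels layout (first line:
#' tab-separated column labels; following lines: row label then the row's
#' lower-triangle entries) as well as a full labelled square matrix.
#'
#' @param path file path, or a character vector of lines.
#' @return symmetric numeric matrix with zero diagonal.
#' @export
read_phylip_matrix <- function(path) {
  lines <- if (length(path) == 1 && file.exists(path))
    readLines(path, warn = FALSE) else path
  lines <- lines[!grepl("^\\s*#", lines)]
  lines <- lines[trimws(lines) != ""]
  if (length(lines) < 2) stop("malformed distance matrix: too few lines", call. = FALSE)
  fields <- strsplit(lines, "\t| +")
  fields <- lapply(fields, function(f) f[f != ""])
  header <- fields[[1]]
  rows <- fields[-1]
  row_labels <- vapply(rows, `[`, "", 1)
  vals <- lapply(rows, function(r) suppressWarnings(as.numeric(r[-1])))
  if (any(vapply(vals, function(v) any(is.na(v)), logical(1)))) {
    stop("malformed distance matrix: non-numeric entry", call. = FALSE)
  }
  nvals <- vapply(vals, length, integer(1))
  if (length(header) == length(rows) && all(nvals == length(header)) &&
      all(header == row_labels)) {
    m <- do.call(rbind, vals)
    dimnames(m) <- list(row_labels, header)
  } else if (all(nvals == seq_along(rows))) {
    labels <- c(header[1], row_labels)
    k <- length(labels)
    m <- matrix(0, k, k, dimnames = list(labels, labels))
    for (i in seq_along(rows)) {
      m[i + 1, seq_len(i)] <- vals[[i]]
    }
    m <- m + t(m)
  } else {
    stop("malformed distance matrix layout", call. = FALSE)
  }
  if (max(abs(m - t(m))) > 1e-8) stop("matrix is not symmetric", call. = FALSE)
  diag(m) <- 0
  m
}

#' Write a labelled square distance matrix
#'
#' @param m labelled symmetric matrix.
#' @param path output path.
#' @param digits rounding for the written entries.
#' @return invisibly, the lines written.
#' @export
write_phylip_matrix <- function(m, path, digits = 6) {
  m <- unclass(m)
  labels <- rownames(m)
  lines <- c(paste(labels, collapse = "\t"),
             vapply(seq_len(nrow(m)), function(i) {
               paste(c(labels[i], formatC(round(m[i, ], digits),
                                          format = "fg", digits = digits)),
                     collapse = "\t")
             }, ""))
  writeLines(lines, path)
  invisible(lines)
}
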