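# Packaged fixtures: the published banding-sequence pool, collection sites,
# genotype and frequency tables and the printed distance matrix, plus the
# format adapters they exercise.

karyopop_extdata <- function(file) {
  p <- system.file("extdata", file, package = "karyopop")
  if (p == "") p <- file.path("inst", "extdata", file)  # pre-install use
  if (!file.exists(p)) stop("fixture not found: ", file, call. = FALSE)
  p
}

#' Convert degrees-minutes-seconds coordinates to decimal degrees
#'
#' @param dms character vector like `"58°11'59.4\"N"`; S and W give negative
#'   values.
#' @return numeric vector of decimal degrees.
#' @export
dms_to_decimal <- function(dms) {
  vapply(dms, function(s) {
    m <- regmatches(s, regexec("^([0-9]+)°([0-9]+)'([0-9.]+)\"([NSEW])$", s))[[1]]
    if (length(m) == 0) stop("malformed DMS coordinate: ", s, call. = FALSE)
    val <- as.numeric(m[2]) + as.numeric(m[3]) / 60 + as.numeric(m[4]) / 3600
    if (m[5] %in% c("S", "W")) -val else val
  }, numeric(1), USE.NAMES = FALSE)
}

.read_tsv <- function(path) {
  utils::read.delim(path, comment.char = "#", quote = "",
                    check.names = FALSE, stringsAsFactors = FALSE,
                    fileEncoding = "UTF-8")
}

#' Read a wide genotype-frequency table
#'
#' First data row `n` carries larvae counts; remaining rows are genotype
#' labels in the published dialect (a `B-chromosome` row, if present, is
#' returned separately as a carrier frequency).
#'
#' @param path TSV path (rows = genotype labels, columns = populations).
#' @return list with `genotypes` (long data frame: population, n, arm, seq1,
#'   seq2, frequency), `b_freq` (named numeric), `populations`.
#' @export
read_genotype_table <- function(path) {
  wide <- .read_tsv(path)
  lab <- wide[[1]]
  pops <- names(wide)[-1]
  n <- as.numeric(wide[lab == "n", -1])
  names(n) <- pops
  b_freq <- setNames(rep(0, length(pops)), pops)
  if (any(lab == "B-chromosome")) {
    b_freq[] <- as.numeric(wide[lab == "B-chromosome", -1])
  }
  rows <- which(!(lab %in% c("n", "B-chromosome")))
  long <- do.call(rbind, lapply(rows, function(r) {
    pair <- parse_genotype_label(lab[r])
    data.frame(population = pops, n = unname(n[pops]),
               arm = .seq_arm(pair[1]), seq1 = pair[1], seq2 = pair[2],
               frequency = as.numeric(wide[r, -1]),
               stringsAsFactors = FALSE)
  }))
  rownames(long) <- NULL
  list(genotypes = long, b_freq = b_freq, populations = pops, n = n)
}

#' Read a wide banding-sequence frequency table
#'
#' @param path TSV path (rows = sequence ids plus an `n` row, columns =
#'   populations).
#' @param tol per-arm frequency-sum tolerance (printed rounding).
#' @return named list of `freq_table` objects, with larvae counts in
#'   `attr(, "n")`.
#' @export
read_frequency_table <- function(path, tol = 0.0025) {
  wide <- .read_tsv(path)
  lab <- .norm_apostrophe(wide[[1]])
  pops <- names(wide)[-1]
  n <- as.numeric(wide[lab == "n", -1])
  names(n) <- pops
  seq_rows <- which(lab != "n")
  ids <- lab[seq_rows]
  arms <- .seq_arm(ids)
  tables <- lapply(pops, function(pp) {
    v <- as.numeric(wide[seq_rows, pp])
    names(v) <- ids
    allele_frequency_table(pp, split(v, arms), tol = tol)
  })
  names(tables) <- pops
  attr(tables, "n") <- n
  tables
}

#' Load the packaged fixtures
#'
#' The banding-sequence pool, the collection-sites table, the genotype and
#' index tables, the banding-sequence frequency tables and the printed
#' distance matrix. Values are kept exactly as printed; known internal
#' inconsistencies of the source tables are surfaced in `$notes` (and as
#' messages when `verbose = TRUE`), not silently reconciled.
#'
#' @param verbose emit the provenance notes as messages.
#' @return list with elements `pool`, `sites`, `table2` (genotype
#'   frequencies, long), `table2_b_freq`, `indices`, `table3` (list of
#'   `freq_table`), `table4` (printed distance matrix), `notes`.
#' @export
load_fixtures <- function(verbose = FALSE) {
  pool <- read_pool(karyopop_extdata("agilis_pool.txt"))
  for (arm in names(pool$catalogues)) {
    v <- validate_arm_pool(pool_arm(pool, arm), pool$catalogues[[arm]])
    if (!v$ok) stop("packaged pool fails validation for arm ", arm,
                    call. = FALSE)
  }
  sites <- .read_tsv(karyopop_extdata("sites.tsv"))
  sites$lat <- dms_to_decimal(sites$lat_dms)
  sites$lon <- dms_to_decimal(sites$lon_dms)
  t2 <- read_genotype_table(karyopop_extdata("table2_genotypes.tsv"))
  indices <- .read_tsv(karyopop_extdata("table2_indices.tsv"))
  table3 <- read_frequency_table(karyopop_extdata("table3_frequencies.tsv"))
  table4 <- read_phylip_matrix(karyopop_extdata("table4_nei.txt"))
  notes <- c(
    "Genotype table: 20 printed data columns under 19 site headers; column YAR-RY is the previously published sample (n = 100) and YAR-RY-OWN this study's own probes (n = 4).",
    "Frequency vs distance tables: the NSK-LI and NSK-OR columns are mutually inconsistent (each reproduces the other's printed distance row, suggesting swapped labels); both kept as printed.",
    "Genotype table: several non-panel columns disagree with the text (e.g. NSK-CH monomorphic for p'agiB1); kept as printed.",
    "YAR-RY larvae count: 4 in the sites table vs 100 in the frequency table header (prior published data); the 100-larvae sample is used for frequency-based work.")
  if (verbose) for (s in notes) message("note: ", s)
  list(pool = pool, sites = sites, table2 = t2$genotypes,
       table2_b_freq = t2$b_freq, indices = indices, table3 = table3,
       table4 = table4, notes = notes)
}

#' Population samples from the packaged genotype table
#'
#' Builds one aggregated `population_sample` per column of the genotype
#' table (frequencies act as weights), ready for [allele_frequencies()] and
#' [pool_census()].
#'
#' @param fx fixtures from [load_fixtures()].
#' @return named list of `population_sample` objects.
#' @export
fixture_samples <- function(fx) {
  split_df <- split(fx$table2, fx$table2$population)
  out <- lapply(names(split_df), function(pp) {
    d <- split_df[[pp]]
    population_sample(pp, n = d$n[1],
                      counts = data.frame(arm = d$arm, seq1 = d$seq1,
                                          seq2 = d$seq2, count = d$frequency,
                                          stringsAsFactors = FALSE),
                      b_chromosomes = round(fx$table2_b_freq[[pp]] * d$n[1]))
  })
  names(out) <- names(split_df)
  out
}
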