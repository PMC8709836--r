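test_that("listing lines parse into ids, oriented runs and the centromere", {
  m <- parse_sequence_line(
    "p'agiB1 25s-q 18n-16a 22a-r 25k-23f 15g-r 21t-i 18o-21h 25p-l 22s-23e 15f-12v C")
  expect_s3_class(m, "sequence_map")
  expect_equal(m$prefix, "p'")
  expect_equal(m$tag, "agi")
  expect_equal(m$arm, "B")
  expect_equal(m$serial, 1)
  expect_equal(nrow(m$runs), 10)
  expect_equal(m$runs$direction[1], "descending")  # 25s-q
  expect_equal(m$runs$direction[3], "ascending")   # 22a-r

  # typographic apostrophe accepted, ASCII stored
  m2 <- parse_sequence_line("p’agiG1 unmapped")
  expect_equal(m2$id, "p'agiG1")

  one <- parse_sequence_line("x'tstA1 1a-3c C")
  expect_equal(nrow(one$runs), 1)
  expect_equal(one$runs$direction, "ascending")
})

test_that("fused two-letter tokens are two-band runs with direction from letter order", {
  m <- parse_sequence_line("p'agiB2 25s-q 18n-16a 22ab 23c-22s 25l-p 21h-18o 21i-t 15r-g 23f-25k 22r-c 23de 15f-12v C")
  fused <- m$runs[m$runs$fused, ]
  expect_equal(nrow(fused), 2)
  expect_equal(fused$s_let, c("a", "d"))
  expect_equal(fused$e_let, c("b", "e"))
  expect_true(all(fused$direction == "ascending"))
  # descending fused token, as in the arm-C listings
  hg <- parse_sequence_line("x'tstC1 6hg 1a-6f C")$runs[1, ]
  expect_equal(hg$direction, "descending")
  expect_error(parse_sequence_line("x'tstA1 22ac C"), "non-adjacent")
})

test_that("malformed lines name the offending token", {
  expect_error(parse_sequence_line("agiB1 1a-2c C"), "id token")
  expect_error(parse_sequence_line("p'agiB1 1a-2c"), "terminal 'C'")
  expect_error(parse_sequence_line("p'agiB1 1a-2c 3a"), "centromere")
  expect_error(parse_sequence_line("p'agiB1 1a-- C"), "token")
  expect_error(parse_sequence_line(""), "empty")
  expect_error(parse_sequence_line("p'agiB1 C 1a-2c C"), "terminal")
})

test_that("catalogue inference: contiguous letters per section, atomic interiors", {
  cat_b <- fx$pool$catalogues$B
  expect_equal(unname(cat_b$letter_count[["22"]]), 19)  # 22a..22s
  expect_equal(unname(cat_b$letter_count[["13"]]), 0)   # only covered inside 15f-12v
  expect_equal(unname(cat_b$letter_count[["14"]]), 0)
  expect_true(all(c("13", "14") %in% cat_b$bands))

  single <- infer_catalogue(list(parse_sequence_line("x'tstA1 1a-2b C")))
  expect_equal(single$bands, c("1a", "2a", "2b"))

  # a section referenced both bare and lettered is a conflict
  expect_error(infer_catalogue(list(parse_sequence_line("x'tstA1 1-2b C"),
                                    parse_sequence_line("x'tstA2 1a-2b C"))),
               "conflict")
})

test_that("range expansion is the canonical interval, oriented by traversal", {
  cat_b <- fx$pool$catalogues$B
  b1 <- pool_sequence(fx$pool, "B1")
  e <- expand_map(b1, cat_b)
  expect_equal(e$band[1:3], c("25s", "25r", "25q"))
  expect_equal(e$sign[1:3], rep(-1L, 3))

  simple <- parse_sequence_line("x'tstA1 1a-d C")
  ec <- expand_map(simple, infer_catalogue(list(simple)))
  expect_equal(ec$band, c("1a", "1b", "1c", "1d"))
  expect_equal(ec$sign, rep(1L, 4))

  # every packaged map expands to exactly the catalogue band set
  for (arm in names(fx$pool$catalogues)) {
    cat_a <- fx$pool$catalogues[[arm]]
    for (m in pool_arm(fx$pool, arm)) {
      expect_setequal(expand_map(m, cat_a)$band, cat_a$bands)
      expect_equal(nrow(expand_map(m, cat_a)), length(cat_a$bands))
    }
  }
})

test_that("explicitly claimed bands take precedence over range interiors", {
  # the arm-C derived listing routes 6g,6h through an explicit fused token
  # while a long range spans their canonical position
  cat_c <- fx$pool$catalogues$C
  c2 <- pool_sequence(fx$pool, "C2")
  e <- expand_map(c2, cat_c)
  expect_equal(sum(e$band %in% c("6g", "6h")), 2)
  run4 <- e$band[e$band %in% c("7d", "7c", "7b", "7a", "6f", "6e", "6d", "6c")]
  expect_equal(length(run4), 8)
})

test_that("arm pools validate as permutations of one band set", {
  for (arm in names(fx$pool$catalogues)) {
    v <- validate_arm_pool(pool_arm(fx$pool, arm), fx$pool$catalogues[[arm]])
    expect_true(v$ok, label = paste("arm", arm, "pool validation"))
  }

  # a constructed defect is reported with its missing bands
  f1 <- pool_sequence(fx$pool, "F1")
  broken <- f1
  broken$id <- "p'agiF9"
  broken$serial <- 9
  broken$runs <- broken$runs[-4, ]  # drop run 18c-a
  v <- validate_arm_pool(list(f1, broken), fx$pool$catalogues$F)
  expect_false(v$ok)
  expect_setequal(v$per_map[["p'agiF9"]]$missing, c("18a", "18b", "18c"))

  # single map passes vacuously
  expect_true(validate_arm_pool(list(f1))$ok)
})

test_that("common refinement yields matching segment alphabets", {
  pool <- fx$pool
  b1 <- pool_sequence(pool, "B1"); b2 <- pool_sequence(pool, "B2")
  cr <- common_refinement(b1, b2, pool$catalogues$B)
  expect_equal(length(cr$target), cr$n_segments)
  expect_setequal(abs(cr$target), cr$ref)
  # B1's run 22a-r splits where B2's fused 22ab ends
  segs <- vapply(cr$segments, function(s) paste(s[1], s[length(s)]), "")
  expect_true("22a 22b" %in% segs)
  expect_true("22c 22r" %in% segs)

  # same map on both sides: identity over the refinement
  cr_id <- common_refinement(b1, b1, pool$catalogues$B)
  amb <- cr_id$ambiguous
  expect_equal(cr_id$target[!amb], cr_id$ref[!amb])

  # segment count invariant under argument order
  cr_rev <- common_refinement(b2, b1, pool$catalogues$B)
  expect_equal(cr_rev$n_segments, cr$n_segments)

  # shared leading runs of F1/F3 map to identical leading segments
  f1 <- pool_sequence(pool, "F1"); f3 <- pool_sequence(pool, "F3")
  crf <- common_refinement(f1, f3, pool$catalogues$F)
  lead <- seq_len(which(crf$target != crf$ref)[1] - 1)
  expect_true(length(lead) >= 1)
  expect_true(all(crf$target[lead] == crf$ref[lead]))
})

test_that("parse/format round-trips every packaged sequence", {
  all_maps <- c(fx$pool$maps, unlist(fx$pool$alternates, recursive = FALSE))
  expect_equal(length(fx$pool$maps), 16)
  for (m in all_maps) {
    expect_true(sequence_maps_equal(m, parse_sequence_line(format_sequence_line(m))),
                label = paste("round-trip", m$id, m$variant))
  }
})

test_that("pool lookups resolve full ids, short forms and mapping versions", {
  expect_equal(pool_sequence(fx$pool, "p'agiB2")$serial, 2)
  expect_equal(pool_sequence(fx$pool, "B2")$id, "p'agiB2")
  expect_error(pool_sequence(fx$pool, "B9"), "not found")
  e1_default <- pool_sequence(fx$pool, "E1")
  expect_equal(e1_default$variant, "GV")
  e1_kv <- pool_sequence(fx$pool, "E1", variant = "KV")
  expect_equal(e1_kv$variant, "KV")
  expect_false(isTRUE(all.equal(e1_kv$runs, e1_default$runs)))
})
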