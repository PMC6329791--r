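test_that("IUPAC expansion follows the degenerate alphabet", {
  expect_setequal(iupac_expand("W"), c("A", "T"))
  expect_setequal(iupac_expand("N"), c("A", "C", "G", "T"))
  expect_identical(iupac_expand("A"), "A")
  expect_setequal(iupac_expand("H"), c("A", "C", "T"))
  expect_setequal(iupac_expand("B"), c("C", "G", "T"))
  expect_setequal(iupac_expand("D"), c("A", "G", "T"))
  expect_error(iupac_expand("X"), "invalid IUPAC")
  expect_error(iupac_expand("n"), "invalid IUPAC")
})

test_that("motif construction enforces alphabet, offset and chemistry", {
  m <- iupac_motif("GANTC", 1, "m6A")
  expect_s3_class(m, "iupac_motif")
  expect_error(iupac_motif("GAXTC", 1, "m6A"), "invalid IUPAC")
  expect_error(iupac_motif("GANTC", 5, "m6A"), "meth_offset")
  expect_error(iupac_motif("GANTC", -1, "m6A"), "meth_offset")
  # methylated base must be chemically possible
  expect_error(iupac_motif("GGTC", 1, "m6A"), "must allow A")
  expect_error(iupac_motif("GATC", 1, "m4C"), "must allow C")
  # degenerate codes containing the required base are allowed
  expect_silent(iupac_motif("GRTC", 1, "m6A"))
})

test_that("motif text syntax round-trips", {
  m <- parse_motif("GmANTC", "m6A")
  expect_identical(m$pattern, "GANTC")
  expect_identical(m$meth_offset, 1L)
  expect_identical(format_motif(m), "GmANTC")
  expect_error(parse_motif("GANTC"), "anchor")
})

test_that("reverse complement maps the duplex partner and is an involution", {
  m <- iupac_motif("AGCNNNNNNCAT", 0, "m6A")
  r <- motif_rc(m)
  expect_identical(r$pattern, "ATGNNNNNNGCT")
  expect_identical(r$meth_offset, 11L)
  expect_identical(r$mod_type, "m6A")
  # GANTC is self-reverse-complementary
  expect_identical(motif_rc(iupac_motif("GANTC", 1, "m6A"))$pattern, "GANTC")
  set.seed(101)
  for (i in 1:50) {
    m <- random_motif()
    rr <- motif_rc(motif_rc(m))
    expect_identical(rr$pattern, m$pattern)
    expect_identical(rr$meth_offset, m$meth_offset)
  }
})

test_that("occurrence counting is strand-specific with 0-based forward starts", {
  # palindrome: one duplex site, two strand entries at the same start
  occ <- motif_occurrences(iupac_motif("GATC", 1, "m6A"), "GGATCC")
  expect_identical(nrow(occ), 2L)
  expect_identical(occ$position, c(1L, 1L))
  expect_setequal(occ$strand, c("+", "-"))
  # degenerate palindrome with overlapping forward and reverse matches
  occ <- motif_occurrences(iupac_motif("GCWGC", 1, "m4C"), "GCAGCTGC")
  expect_identical(occ$position[occ$strand == "+"], c(0L, 3L))
  expect_identical(occ$position[occ$strand == "-"], c(0L, 3L))
  # reverse-strand-only match
  occ <- motif_occurrences(iupac_motif("ACGAG", 3, "m6A"), "CTCGT")
  expect_identical(nrow(occ), 1L)
  expect_identical(occ$strand, "-")
  expect_identical(occ$position, 0L)
  # empty and too-short sequences yield empty results, not errors
  expect_identical(nrow(motif_occurrences(iupac_motif("GATC", 1, "m6A"), "")), 0L)
  expect_identical(nrow(motif_occurrences(iupac_motif("GATC", 1, "m6A"), "GA")), 0L)
})

test_that("non-ACGT sequence characters never match, even pattern N", {
  m <- iupac_motif("GANTC", 1, "m6A")
  # a literal N in the subject is not a wildcard
  expect_identical(nrow(motif_occurrences(m, "GANTC")), 0L)
  # the ACGT-only window still matches (palindromic pattern: both strands)
  occ <- motif_occurrences(m, "GACTCNNNNN")
  expect_identical(occ$position, c(0L, 0L))
})

test_that("occurrences agree with a brute-force window oracle", {
  set.seed(202)
  for (i in 1:8) {
    seq <- random_dna(10000, gc = runif(1, 0.3, 0.7))
    m <- random_motif()
    got <- motif_occurrences(m, seq)
    want <- oracle_occurrences(m$pattern, seq)
    got <- got[order(got$position, got$strand), ]
    want <- want[order(want$position, want$strand), ]
    expect_equal(got$position, want$position)
    expect_equal(got$strand, want$strand)
  }
})

test_that("self-reverse-complementary motifs have equal strand counts", {
  set.seed(303)
  pal <- list(iupac_motif("GATC", 1, "m6A"), iupac_motif("TTAA", 3, "m6A"),
              iupac_motif("GCWGC", 1, "m4C"), iupac_motif("GAANNNNTTC", 1, "m6A"))
  for (m in pal) {
    seq <- random_dna(20000)
    occ <- motif_occurrences(m, seq)
    expect_identical(sum(occ$strand == "+"), sum(occ$strand == "-"))
  }
})

test_that("methylated-base coordinates map through strand geometry", {
  # AGGA on the minus strand of TCCT: motif A|GGA methylated at offset 0
  m <- iupac_motif("AGGA", 0, "m6A")
  mp <- motif_meth_positions(m, "TCCT")
  expect_identical(mp$strand, "-")
  expect_identical(mp$position, 3L)  # pairs with the final A of the motif
  mp <- motif_meth_positions(iupac_motif("GATC", 1, "m6A"), "GATC")
  expect_identical(mp$position[mp$strand == "+"], 1L)
  expect_identical(mp$position[mp$strand == "-"], 2L)
})

test_that("positionwise intersection flags conflicts and overhangs", {
  m1 <- iupac_motif("GMAGCTKC", 4, "m4C")
  m2 <- iupac_motif("HCAGCTKC", 4, "m4C")
  pw <- positionwise_intersection(m1, m2)
  expect_identical(sum(pw$empty), 1L)     # G vs H at the first position
  expect_identical(sum(pw$overhang), 0L)
  pw <- positionwise_intersection(m1, m1)
  expect_identical(sum(pw$empty), 0L)
  expect_identical(sum(pw$overhang), 0L)
  m3 <- iupac_motif("BGMAGCTGD", 5, "m4C")
  pw <- positionwise_intersection(m1, m3)
  expect_identical(sum(pw$empty), 1L)     # C vs D
  expect_identical(sum(pw$overhang), 1L)  # the leading B
})

test_that("reverse-complement compatibility detects duplex motif pairs", {
  a <- iupac_motif("AGCNNNNNNCAT", 0, "m6A")
  b <- iupac_motif("ATGNNNNNNGCT", 0, "m6A")
  expect_true(rc_compatible(a, b))
  e <- iupac_motif("CAANNNNNNNNCTTG", 2, "m6A")
  f <- iupac_motif("CAAGNNNNNNNDTTG", 2, "m6A")
  expect_true(rc_compatible(e, f))  # D within N at the one differing position
  expect_false(rc_compatible(iupac_motif("GANTC", 1, "m6A"),
                             iupac_motif("TTAA", 3, "m6A")))
  # modification classes must agree
  expect_false(rc_compatible(iupac_motif("AGCT", 2, "m4C"),
                             iupac_motif("AGCT", 0, "m6A")))
})

test_that("similarity merging tolerates one conflict and one overhang base", {
  g <- iupac_motif("GMAGCTKC", 4, "m4C")
  h <- iupac_motif("HCAGCTKC", 4, "m4C")
  b <- iupac_motif("BGMAGCTGD", 5, "m4C")
  expect_true(similarity_mergeable(g, h))
  expect_true(similarity_mergeable(g, b))
  expect_false(similarity_mergeable(
    iupac_motif("AGCNNNNNNCAT", 0, "m6A"),
    iupac_motif("AGCNNNNNNGTG", 0, "m6A")))
  expect_false(similarity_mergeable(
    iupac_motif("AGGNNNNNRTTT", 0, "m6A"),
    iupac_motif("AGGNNNNNCTAA", 0, "m6A")))
  # same modification type required
  expect_false(similarity_mergeable(iupac_motif("GATC", 1, "m6A"),
                                    iupac_motif("GCTC", 1, "m4C")))
  # distinct spacer motifs must not merge through their N runs
  expect_false(similarity_mergeable(
    iupac_motif("TTAGNNNNNCCT", 2, "m6A"),
    iupac_motif("GYTANNNNNNNTTRG", 3, "m6A")))
})

test_that("dedupe_and_group deduplicates, marks novelty, merges groups", {
  # one known motif shared by three genomes
  df <- data.frame(genome_id = c("a", "b", "c"), pattern = "GANTC",
                   meth_offset = 1, mod_type = "m6A")
  g <- dedupe_and_group(df, reference = "GANTC")
  expect_identical(g$n_distinct, 1L)
  expect_identical(g$n_novel_groups, 0L)
  # two novel duplex partners collapse to one rc_pair group
  df <- data.frame(genome_id = "a", pattern = c("AGCNNNNNNCAT", "ATGNNNNNNGCT"),
                   meth_offset = 0, mod_type = "m6A")
  g <- dedupe_and_group(df, reference = "GANTC")
  expect_identical(g$n_distinct, 2L)
  expect_identical(g$n_novel_groups, 1L)
  expect_identical(g$groups[[1]]$kind, "rc_pair")
  # known status also granted via the reverse complement of a reference entry
  df <- data.frame(genome_id = "a", pattern = "AGGA", meth_offset = 0,
                   mod_type = "m6A")
  g <- dedupe_and_group(df, reference = "TCCT")
  expect_true(g$motifs$reference_known)
  expect_error(dedupe_and_group(df[0, ]), "empty")
})

test_that("dedupe_and_group is order-invariant and idempotent", {
  df <- fixture_motif_df()
  ref <- fixture_reference()
  base <- dedupe_and_group(df, ref)
  set.seed(404)
  for (i in 1:5) {
    g <- dedupe_and_group(df[sample(nrow(df)), ], ref)
    expect_identical(g$motifs, base$motifs)
    expect_identical(g$n_novel_groups, base$n_novel_groups)
  }
  # duplicating rows changes nothing
  g <- dedupe_and_group(rbind(df, df), ref)
  expect_identical(g$n_distinct, base$n_distinct)
  expect_identical(g$n_novel_groups, base$n_novel_groups)
})
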