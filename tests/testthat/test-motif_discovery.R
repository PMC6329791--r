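test_that("context extraction centres the methylated base and honours strand", {
  contigs <- c(c1 = "AAAAAAAAAAGATCAAAAAAAAAA")
  # + site at the A of GATC (position 11)
  s <- data.frame(contig_id = "c1", position = 11L, strand = "+")
  ctx <- extract_contexts(s, contigs, flank = 3)
  expect_identical(ctx, "AAGATCA")
  # - site context is the reverse complement of the forward window
  s <- data.frame(contig_id = "c1", position = 12L, strand = "-")
  ctx <- extract_contexts(s, contigs, flank = 3)
  expect_identical(ctx, as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(contigs[[1]], 10, 16)))))
  # windows truncated by the contig end are dropped
  s <- data.frame(contig_id = "c1", position = c(0L, 23L, 11L), strand = "+")
  expect_identical(length(extract_contexts(s, contigs, flank = 3)), 1L)
  # off-contig sites are an error, unknown contigs too
  expect_error(extract_contexts(data.frame(contig_id = "c1", position = 99L,
                                           strand = "+"), contigs), "outside")
  expect_error(extract_contexts(data.frame(contig_id = "zz", position = 1L,
                                           strand = "+"), contigs), "unknown contig")
})

test_that("planted-site contexts carry the motif bases at fixed offsets", {
  set.seed(21)
  contigs <- c(c1 = random_dna(50000))
  m <- iupac_motif("GANTC", 1, "m6A")
  mp <- motif_meth_positions(m, contigs[[1]])
  mp$contig_id <- "c1"
  ctx <- extract_contexts(mp, contigs, flank = 10)
  expect_gt(length(ctx), 100)
  mat <- do.call(rbind, strsplit(ctx, ""))
  expect_true(all(mat[, 11] == "A"))
  expect_true(all(mat[, 10] == "G"))
  expect_true(all(mat[, 13] == "T"))
  expect_true(all(mat[, 14] == "C"))
})

test_that("discovery recovers a single planted system exactly", {
  run <- recovery_run(seed = 1)
  found <- run$per_genome[[2]]$found  # GANTC genome
  pats <- vapply(found, function(m) m$pattern, "")
  expect_true("GANTC" %in% pats)
  hit <- found[[match("GANTC", pats)]]
  expect_identical(hit$meth_offset, 1L)
  expect_identical(hit$mod_type, "m6A")
})

test_that("discovery separates two co-planted systems without spurious calls", {
  spec <- community_spec(n_genomes = 1, genome_length_bp = 150000,
                         gc_content = 0.45, abundance = 1, coverage_mean = 30,
                         systems = list(list(
                           list(motif = iupac_motif("TTAA", 3, "m6A"), fraction = 0.9),
                           list(motif = iupac_motif("GATC", 1, "m6A"), fraction = 0.9))),
                         seed = 22)
  sim <- simulate_community(spec)
  sites <- call_sites(sim$kinetics)
  found <- discover_genome_motifs(sites, sim$genomes$contigs)
  sm <- do.call(rbind, lapply(found, summarize_motif,
                              contigs = sim$genomes$contigs, sites = sites,
                              kinetics = sim$kinetics, genome_id = "g1"))
  sm <- filter_motifs(sm)
  expect_setequal(sm$motif, c("TTAA", "GATC"))
})

test_that("uniformly random called sites yield no motif", {
  set.seed(23)
  contigs <- c(c1 = random_dna(100000))
  fake <- data.frame(contig_id = "c1",
                     position = sample(0:99999, 800),
                     strand = sample(c("+", "-"), 800, replace = TRUE),
                     qv = runif(800, 30, 60))
  found <- discover_genome_motifs(fake, contigs)
  expect_length(found, 0)
})

test_that("degenerate positions are recovered as IUPAC codes", {
  run <- recovery_run(seed = 1)
  found <- run$per_genome[[3]]$found  # GCWGC genome
  pats <- vapply(found, function(m) m$pattern, "")
  expect_true("GCWGC" %in% pats)
  hit <- found[[match("GCWGC", pats)]]
  expect_identical(hit$mod_type, "m4C")
  expect_identical(hit$meth_offset, 1L)
})

test_that("the occurrence/fraction filter applies strict inequalities", {
  df <- data.frame(motif = c("a", "b", "c", "d"),
                   n_motif_sites = c(49L, 5000L, 50L, 276L),
                   ratio_pct = c(90, 0.5, 1.0, 29.0))
  kept <- filter_motifs(df)
  # <50 occurrences excluded despite high ratio; <1% excluded despite support;
  # exact boundary values 50 and 1.0% are retained
  expect_setequal(kept$motif, c("c", "d"))
})

test_that("summaries reproduce printed ratio arithmetic", {
  expect_identical(methylation_ratio(1813, 2070), 87.6)
  expect_identical(methylation_ratio(72730, 77932), 93.3)
  expect_identical(methylation_ratio(0, 100), 0)
  expect_error(methylation_ratio(5, 0))
  expect_error(methylation_ratio(101, 100))
})

test_that("summarize_motif counts occurrences and coinciding called sites", {
  contigs <- c(c1 = "AAGATCAAGATCAA", c2 = "TTGATCTT")
  m <- iupac_motif("GATC", 1, "m6A")
  # methylated positions: c1 +3/+10 (plus strand), c1 -4/-11, c2 +3, c2 -4
  sites <- data.frame(contig_id = c("c1", "c1", "c2"),
                      position = c(3L, 4L, 3L),
                      strand = c("+", "-", "+"),
                      qv = c(40, 35, 50), coverage = c(30L, 31L, 29L),
                      effect = 1.2)
  s <- summarize_motif(m, contigs, sites, genome_id = "g")
  expect_identical(s$n_motif_sites, 6L)
  expect_identical(s$n_meth_sites, 3L)
  expect_identical(s$ratio_pct, 50)
  expect_equal(s$mean_qv, mean(c(40, 35, 50)))
  expect_error(summarize_motif(iupac_motif("ACGCGCGT", 3, "m4C"), contigs, sites),
               "no occurrences")
})

test_that("summaries are additive under contig splitting", {
  set.seed(24)
  whole <- c(w = random_dna(40000))
  halves <- c(h1 = substr(whole[[1]], 1, 20000),
              h2 = substr(whole[[1]], 20001, 40000))
  m <- iupac_motif("GANTC", 1, "m6A")
  mp <- motif_meth_positions(m, whole[[1]])
  picked <- mp[runif(nrow(mp)) < 0.7, ]
  sites_w <- data.frame(contig_id = "w", position = picked$position,
                        strand = picked$strand, qv = 40, coverage = 30L,
                        effect = 1.3)
  in_h2 <- picked$position >= 20000
  sites_h <- data.frame(contig_id = ifelse(in_h2, "h2", "h1"),
                        position = ifelse(in_h2, picked$position - 20000L,
                                          picked$position),
                        strand = picked$strand, qv = 40, coverage = 30L,
                        effect = 1.3)
  a <- summarize_motif(m, whole, sites_w)
  b <- summarize_motif(m, halves, sites_h)
  # the split severs only motifs straddling the cut (at most a few)
  expect_lte(abs(a$n_motif_sites - b$n_motif_sites), 4L)
  expect_lte(abs(a$n_meth_sites - b$n_meth_sites), 4L)
})

test_that("recovered fractions track planted fractions on the benchmark", {
  run <- recovery_run(seed = 1)
  planted <- list(g1 = c(TTAA = 0.80), g2 = c(GANTC = 0.90),
                  g3 = c(GCWGC = 0.85), g4 = c(GATC = 0.95))
  for (g in names(planted)) {
    sm <- run$per_genome[[as.integer(sub("g", "", g))]]$summary
    for (pat in names(planted[[g]])) {
      row <- sm[sm$motif == pat, ]
      expect_identical(nrow(row), 1L)
      expect_lt(abs(row$ratio_testable_pct - 100 * planted[[g]][[pat]]), 5)
    }
  }
})
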