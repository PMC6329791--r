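# Independent oracles: these re-derive expected values from first principles
# and share no code path with the package implementation.

# IUPAC expansion table written out by hand (not the package's table)
ORACLE_IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

oracle_revcomp_seq <- function(seq) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  chars <- rev(strsplit(seq, "")[[1]])
  paste(ifelse(chars %in% names(comp), comp[chars], "?"), collapse = "")
}

# window-by-window occurrence scan on both strands; 0-based forward starts
oracle_occurrences <- function(pattern, seq) {
  pat <- strsplit(pattern, "")[[1]]
  w <- length(pat)
  scan <- function(s) {
    chars <- strsplit(s, "")[[1]]
    L <- length(chars)
    if (L < w) return(integer(0))
    hits <- integer(0)
    for (p in 0:(L - w)) {
      ok <- TRUE
      for (j in seq_len(w)) {
        if (!chars[p + j] %in% ORACLE_IUPAC[[pat[j]]]) { ok <- FALSE; break }
      }
      if (ok) hits <- c(hits, p)
    }
    hits
  }
  L <- nchar(seq)
  fwd <- scan(seq)
  rev_on_rc <- scan(oracle_revcomp_seq(seq))
  rev_fwd <- sort(L - rev_on_rc - w)
  data.frame(position = c(fwd, rev_fwd),
             strand = rep(c("+", "-"), c(length(fwd), length(rev_fwd))),
             stringsAsFactors = FALSE)
}

# upper-tail t probability by numerical integration of the density; for
# t > 1 the substitution x = t/s maps the tail onto (0, 1], which keeps the
# quadrature accurate even for very small tail probabilities
oracle_qv <- function(mean_ipd, sd_ipd, coverage, sd_floor = 0.1) {
  tstat <- mean_ipd * sqrt(coverage) / max(sd_ipd, sd_floor)
  df <- coverage - 1
  p <- if (tstat > 1) {
    stats::integrate(function(s) stats::dt(tstat / s, df) * tstat / s^2,
                     lower = 0, upper = 1, rel.tol = 1e-12)$value
  } else {
    stats::integrate(function(x) stats::dt(x, df), lower = tstat,
                     upper = Inf, rel.tol = 1e-12)$value
  }
  -10 * log10(p)
}

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

random_motif <- function(max_len = 16) {
  len <- sample(4:max_len, 1)
  pat <- sample(names(ORACLE_IUPAC), len, replace = TRUE,
                prob = c(rep(6, 4), rep(1, 10), 4))
  off <- sample(len, 1) - 1L
  centre <- sample(c("A", "C"), 1)
  pat[off + 1L] <- centre
  iupac_motif(paste(pat, collapse = ""), off,
              if (centre == "A") "m6A" else "m4C")
}

fixture_motif_df <- function() {
  tab <- load_motif_table()
  data.frame(genome_id = tab$genome_id, pattern = tab$motif,
             meth_offset = tab$meth_offset, mod_type = tab$mod_type,
             stringsAsFactors = FALSE)
}

fixture_reference <- function() {
  tab <- load_motif_table()
  unique(tab$motif[tab$in_rebase == "Yes"])
}

# one shared recovery-benchmark run per test session (the heaviest fixture)
recovery_run_cache <- new.env(parent = emptyenv())
recovery_run <- function(seed = 1) {
  key <- paste0("s", seed)
  if (!is.null(recovery_run_cache[[key]])) return(recovery_run_cache[[key]])
  spec <- example_recovery_spec(seed = seed)
  sim <- simulate_community(spec)
  sites <- call_sites(sim$kinetics)
  per_genome <- lapply(seq_len(spec$n_genomes), function(g) {
    gid <- paste0("g", g)
    cids <- sim$genomes$contig_map$contig_id[sim$genomes$contig_map$genome_id == gid]
    ctgs <- sim$genomes$contigs[cids]
    gs <- sites[sites$contig_id %in% cids, , drop = FALSE]
    gk <- sim$kinetics[sim$kinetics$contig_id %in% cids, , drop = FALSE]
    found <- discover_genome_motifs(gs, ctgs)
    sm <- if (length(found)) {
      s <- do.call(rbind, lapply(found, summarize_motif, contigs = ctgs,
                                 sites = gs, kinetics = gk, genome_id = gid))
      filter_motifs(s)
    } else NULL
    list(found = found, summary = sm)
  })
  res <- list(spec = spec, sim = sim, sites = sites, per_genome = per_genome)
  recovery_run_cache[[key]] <- res
  res
}
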