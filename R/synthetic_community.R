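#' Specify a synthetic microbial community with planted methylation systems
#'
#' Defines a seeded mock community standing in for an environmental sample:
#' per-genome length, GC content and compositional (Markov) bias, relative
#' abundances driving subread coverage, and per-genome methylation systems
#' (a degenerate motif plus a partial methylation fraction). Kinetic effect
#' sizes follow the detectability ordering of the three modification types
#' (m6A > m4C > m5C).
#'
#' The default community has four genomes of 200 kb at abundances 8:4:2:1
#' with a community-mean subread coverage of 30 per strand, so the abundant
#' genomes exceed the >25x per-strand detection guidance while the rare ones
#' drop below it.
#'
#' @param n_genomes Number of genomes.
#' @param genome_length_bp Genome length(s), recycled across genomes.
#' @param gc_content Per-genome GC fraction in `[0, 1]`.
#' @param markov_order Order (0-3) of the per-genome composition model.
#' @param abundance Positive relative abundances (normalised internally).
#' @param systems Per-genome list of methylation systems; each system is a
#'   `list(motif = iupac_motif, fraction = <methylated fraction in [0,1]>)`.
#' @param coverage_mean Community-mean subreads per strand; genome `i` gets
#'   `coverage_mean * abundance[i] / mean(abundance)`.
#' @param ipd_sigma Per-subread standard deviation of the log2 interpulse
#'   duration (IPD) ratio.
#' @param ipd_delta Named mean log2 IPD-ratio shifts at methylated sites.
#' @param frag_meanlog,frag_sdlog Log-normal contig length parameters.
#' @param min_contig_bp Minimum contig length.
#' @param seed Integer seed; every downstream draw is a pure function of the
#'   spec and this seed.
#' @return Object of class `community_spec`.
#' @export
community_spec <- function(n_genomes = 4,
                           genome_length_bp = 200000,
                           gc_content = c(0.35, 0.45, 0.55, 0.65),
                           markov_order = 0,
                           abundance = c(8, 4, 2, 1),
                           systems = default_systems(),
                           coverage_mean = 30,
                           ipd_sigma = 1.0,
                           ipd_delta = c(m6A = 1.3, m4C = 0.8, m5C = 0.25),
                           frag_meanlog = log(30000),
                           frag_sdlog = 0.6,
                           min_contig_bp = 5000,
                           seed = 1L) {
  genome_length_bp <- rep_len(as.integer(genome_length_bp), n_genomes)
  gc_content <- rep_len(gc_content, n_genomes)
  abundance <- rep_len(abundance, n_genomes)
  stopifnot(n_genomes >= 1, all(genome_length_bp > 0),
            all(gc_content >= 0 & gc_content <= 1),
            markov_order %in% 0:3,
            all(abundance > 0),
            coverage_mean > 0, ipd_sigma > 0, all(ipd_delta >= 0),
            length(systems) == n_genomes)
  for (g in systems) for (s in g) {
    stopifnot(inherits(s$motif, "iupac_motif"),
              s$fraction >= 0, s$fraction <= 1)
  }
  structure(list(n_genomes = n_genomes, genome_length_bp = genome_length_bp,
                 gc_content = gc_content, markov_order = as.integer(markov_order),
                 abundance = abundance / sum(abundance), systems = systems,
                 coverage_mean = coverage_mean, ipd_sigma = ipd_sigma,
                 ipd_delta = ipd_delta, frag_meanlog = frag_meanlog,
                 frag_sdlog = frag_sdlog, min_contig_bp = min_contig_bp,
                 seed = as.integer(seed)),
            class = "community_spec")
}

#' Default planted methylation systems
#'
#' One disjoint system set per genome so that per-contig methylation profiles
#' separate the genomes: a Dam-like GATC plus a weak m5C system in the most
#' abundant genome, and HinfI-like, TseI-like and MseI-like systems in the
#' others. Fractions sit in the partially-methylated range observed for real
#' prokaryotic methylomes.
#'
#' @return List (one element per genome) of system lists.
#' @export
default_systems <- function() {
  list(
    list(list(motif = iupac_motif("GATC", 1, "m6A"), fraction = 0.95),
         list(motif = iupac_motif("CCWGG", 1, "m5C"), fraction = 0.90)),
    list(list(motif = iupac_motif("GANTC", 1, "m6A"), fraction = 0.90)),
    list(list(motif = iupac_motif("GCWGC", 1, "m4C"), fraction = 0.85)),
    list(list(motif = iupac_motif("TTAA", 3, "m6A"), fraction = 0.90))
  )
}

#' Benchmark community for parameter-recovery evaluation
#'
#' An equal-abundance four-genome community at 30 subreads per strand — just
#' above the >25x detection guidance — with one methylation system per
#' genome, planted in a genome whose base composition suits the motif (an
#' AT-rich motif in the AT-rich genome, and so on) so that recovery measures
#' detection power rather than occurrence starvation. Fractions span the
#' partially-methylated range 0.80-0.95; the GC-richest genome additionally
#' carries an m5C system whose weak kinetic signal probes the
#' m6A > m4C > m5C sensitivity ordering.
#'
#' @param seed Integer seed.
#' @return A [community_spec()].
#' @export
example_recovery_spec <- function(seed = 1L) {
  community_spec(
    abundance = c(1, 1, 1, 1),
    coverage_mean = 30,
    systems = list(
      list(list(motif = iupac_motif("TTAA", 3, "m6A"), fraction = 0.80)),
      list(list(motif = iupac_motif("GANTC", 1, "m6A"), fraction = 0.90)),
      list(list(motif = iupac_motif("GCWGC", 1, "m4C"), fraction = 0.85)),
      list(list(motif = iupac_motif("GATC", 1, "m6A"), fraction = 0.95),
           list(motif = iupac_motif("CCWGG", 1, "m5C"), fraction = 0.90))),
    seed = seed)
}

# per-genome mean subread coverage per strand
genome_coverage <- function(spec) {
  spec$coverage_mean * spec$abundance / mean(spec$abundance)
}

# derive independent stage seeds from the spec seed (kept below 2^31)
stage_seed <- function(seed, stage) (as.integer(seed) %% 100000L) * 7919L + stage

sample_markov_sequence <- function(L, gc, order, seed_probs_rng = NULL) {
  base_p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  bases <- c("A", "C", "G", "T")
  if (order == 0) {
    return(paste(sample(bases, L, replace = TRUE, prob = base_p), collapse = ""))
  }
  # random per-genome transition kernel around the base composition: a
  # Dirichlet draw per k-mer context gives each genome its own k-mer signature
  n_ctx <- 4L^order
  alpha <- matrix(rep(base_p * 20, each = n_ctx), nrow = n_ctx)
  gam <- matrix(rgamma(n_ctx * 4L, shape = alpha), nrow = n_ctx)
  trans <- gam / rowSums(gam)
  cum <- t(apply(trans, 1L, cumsum))
  out <- integer(L)
  out[seq_len(order)] <- sample.int(4L, order, replace = TRUE, prob = base_p)
  u <- runif(L)
  pow <- 4L^(seq_len(order) - 1L)
  ctx <- sum((out[seq_len(order)] - 1L) * pow) + 1L
  for (i in (order + 1L):L) {
    b <- findInterval(u[i], cum[ctx, ], left.open = TRUE) + 1L
    out[i] <- b
    ctx <- (ctx - 1L) %/% 4L + (b - 1L) * pow[order] + 1L
  }
  paste(bases[out], collapse = "")
}

#' Generate genome sequences and fragment them into contigs
#'
#' Genomes are sampled from per-genome Markov composition models and cut into
#' contigs with log-normal lengths (minimum `min_contig_bp`); a terminal
#' remainder shorter than the minimum is merged into the preceding contig.
#' Deterministic given the spec seed.
#'
#' @param spec A `community_spec`.
#' @return List with `contigs` (named character vector of contig sequences),
#'   `contig_map` (`data.frame`: `contig_id`, `genome_id`, `length`), and
#'   `genomes` (full genome sequences).
#' @export
generate_genomes <- function(spec) {
  stopifnot(inherits(spec, "community_spec"))
  longest <- max(c(1L, unlist(lapply(spec$systems, function(g)
    vapply(g, function(s) nchar(s$motif$pattern), 1L)))))
  if (any(spec$genome_length_bp < longest)) {
    stop("genome shorter than the longest planted motif")
  }
  set.seed(stage_seed(spec$seed, 1L))
  genomes <- character(spec$n_genomes)
  contigs <- character(0)
  map <- list()
  for (g in seq_len(spec$n_genomes)) {
    gid <- sprintf("g%d", g)
    L <- spec$genome_length_bp[g]
    genomes[g] <- sample_markov_sequence(L, spec$gc_content[g], spec$markov_order)
    # fragmentation
    lens <- integer(0); total <- 0L
    while (total < L) {
      l <- max(spec$min_contig_bp,
               as.integer(round(exp(rnorm(1, spec$frag_meanlog, spec$frag_sdlog)))))
      l <- min(l, L - total)
      lens <- c(lens, l); total <- total + l
    }
    if (length(lens) > 1L && lens[length(lens)] < spec$min_contig_bp) {
      lens[length(lens) - 1L] <- lens[length(lens) - 1L] + lens[length(lens)]
      lens <- lens[-length(lens)]
    }
    starts <- cumsum(c(1L, lens[-length(lens)]))
    ids <- sprintf("%s_c%02d", gid, seq_along(lens))
    for (k in seq_along(lens)) {
      contigs[ids[k]] <- substr(genomes[g], starts[k], starts[k] + lens[k] - 1L)
    }
    map[[g]] <- data.frame(contig_id = ids, genome_id = gid, length = lens,
                           stringsAsFactors = FALSE)
  }
  names(genomes) <- sprintf("g%d", seq_len(spec$n_genomes))
  list(contigs = contigs, contig_map = do.call(rbind, map), genomes = genomes)
}

#' Plant partial methylation at motif occurrences
#'
#' Every strand-specific occurrence of each planted motif is methylated
#' independently with the system's methylation fraction, except that
#' self-reverse-complementary motifs are methylated jointly on both strands
#' of a duplex site (one Bernoulli draw per site), mirroring double-strand
#' methylation by RM systems.
#'
#' @param genomes Result of [generate_genomes()].
#' @param spec A `community_spec`.
#' @return Truth table: list with `sites` (`data.frame`: `contig_id`,
#'   `position` of the methylated base, `strand`, `genome_id`, `pattern`,
#'   `mod_type`) and `contig_map`.
#' @export
plant_methylation <- function(genomes, spec) {
  stopifnot(inherits(spec, "community_spec"))
  set.seed(stage_seed(spec$seed, 2L))
  out <- list()
  for (g in seq_len(spec$n_genomes)) {
    gid <- sprintf("g%d", g)
    cids <- genomes$contig_map$contig_id[genomes$contig_map$genome_id == gid]
    for (sys in spec$systems[[g]]) {
      m <- sys$motif
      for (cid in cids) {
        seq <- genomes$contigs[[cid]]
        mp <- motif_meth_positions(m, seq)
        if (!nrow(mp)) next
        if (is_self_rc(m)) {
          # joint duplex draw: occurrences come in +/- pairs per start site
          occ <- motif_occurrences(m, seq)
          starts <- unique(occ$position)
          keep_start <- starts[runif(length(starts)) < sys$fraction]
          occ <- occ[occ$position %in% keep_start, , drop = FALSE]
          L <- nchar(m$pattern)
          mp <- data.frame(position = ifelse(occ$strand == "+",
                                             occ$position + m$meth_offset,
                                             occ$position + L - 1L - m$meth_offset),
                           strand = occ$strand, stringsAsFactors = FALSE)
        } else {
          mp <- mp[runif(nrow(mp)) < sys$fraction, , drop = FALSE]
        }
        if (nrow(mp)) {
          out[[length(out) + 1L]] <- data.frame(
            contig_id = cid, position = mp$position, strand = mp$strand,
            genome_id = gid, pattern = m$pattern, mod_type = m$mod_type,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  sites <- if (length(out)) do.call(rbind, out) else
    data.frame(contig_id = character(0), position = integer(0),
               strand = character(0), genome_id = character(0),
               pattern = character(0), mod_type = character(0))
  rownames(sites) <- NULL
  list(sites = sites, contig_map = genomes$contig_map)
}

#' Simulate per-site subread kinetic summaries
#'
#' For every contig position and strand, subread coverage is Poisson with the
#' genome's abundance-scaled mean; per-subread log2 IPD ratios are normal with
#' standard deviation `ipd_sigma`, centred at 0 for unmethylated sites and at
#' the modification-type effect size for methylated ones. Sites are emitted as
#' summary statistics (coverage, mean, sd) drawn from the exact sampling
#' distributions of the subread mean and standard deviation.
#'
#' @param genomes Result of [generate_genomes()].
#' @param truth Result of [plant_methylation()].
#' @param spec A `community_spec`.
#' @return `data.frame` with one row per (contig, position, strand):
#'   `contig_id`, `position`, `strand`, `coverage`, `mean_log2_ipd_ratio`,
#'   `sd_log2_ipd_ratio`.
#' @export
simulate_kinetics <- function(genomes, truth, spec) {
  stopifnot(inherits(spec, "community_spec"))
  set.seed(stage_seed(spec$seed, 3L))
  cov_g <- genome_coverage(spec)
  names(cov_g) <- sprintf("g%d", seq_len(spec$n_genomes))
  sigma <- spec$ipd_sigma
  res <- vector("list", nrow(genomes$contig_map) * 2L)
  k <- 0L
  for (i in seq_len(nrow(genomes$contig_map))) {
    cid <- genomes$contig_map$contig_id[i]
    gid <- genomes$contig_map$genome_id[i]
    L <- genomes$contig_map$length[i]
    tsites <- truth$sites[truth$sites$contig_id == cid, , drop = FALSE]
    for (strand in c("+", "-")) {
      mu <- numeric(L)
      ts <- tsites[tsites$strand == strand, , drop = FALSE]
      if (nrow(ts)) mu[ts$position + 1L] <- spec$ipd_delta[ts$mod_type]
      cov <- rpois(L, cov_g[[gid]])
      mean_ipd <- mu + sigma * rnorm(L) / sqrt(pmax(cov, 1L))
      sd_ipd <- numeric(L)
      idx <- cov >= 2L
      df <- cov[idx] - 1L
      sd_ipd[idx] <- sigma * sqrt(rchisq(sum(idx), df) / df)
      k <- k + 1L
      res[[k]] <- data.frame(contig_id = cid, position = seq_len(L) - 1L,
                             strand = strand, coverage = cov,
                             mean_log2_ipd_ratio = mean_ipd,
                             sd_log2_ipd_ratio = sd_ipd,
                             stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, res[seq_len(k)])
  rownames(out) <- NULL
  out
}

#' Run the full generator: genomes, planted truth and kinetics
#'
#' @param spec A `community_spec`.
#' @return List with `spec`, `genomes`, `truth`, `kinetics`.
#' @export
simulate_community <- function(spec = community_spec()) {
  genomes <- generate_genomes(spec)
  truth <- plant_methylation(genomes, spec)
  kinetics <- simulate_kinetics(genomes, truth, spec)
  list(spec = spec, genomes = genomes, truth = truth, kinetics = kinetics)
}
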