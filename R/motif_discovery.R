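#' Extract centred sequence contexts around called sites
#'
#' Returns the `2 * flank + 1` window around each called site on the called
#' strand (reverse-complemented for minus-strand sites), with the methylated
#' base at the centre. Windows truncated by a contig end are dropped.
#'
#' @param sites `data.frame` with `contig_id`, `position`, `strand`.
#' @param contigs Named character vector of contig sequences.
#' @param flank Bases kept on each side of the called position.
#' @return Character vector of context strings.
#' @export
extract_contexts <- function(sites, contigs, flank = 10) {
  stopifnot(is.data.frame(sites), all(c("contig_id", "position", "strand") %in% names(sites)))
  if (!nrow(sites)) return(character(0))
  if (any(!sites$contig_id %in% names(contigs))) stop("site on unknown contig")
  len <- nchar(contigs)[sites$contig_id]
  if (any(sites$position < 0 | sites$position >= len)) stop("site position outside contig")
  keep <- sites$position >= flank & sites$position + flank < len
  s <- sites[keep, , drop = FALSE]
  if (!nrow(s)) return(character(0))
  win <- substring(contigs[s$contig_id], s$position - flank + 1L,
                   s$position + flank + 1L)
  neg <- s$strand == "-"
  if (any(neg)) {
    win[neg] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(win[neg])))
  }
  unname(win)
}

# information content (bits) of a base-frequency vector over A,C,G,T
ic_bits <- function(p) {
  p <- p[p > 0]
  2 + sum(p * log2(p))
}

# minimal IUPAC code over a frequency vector: bases with share >= min_share,
# most frequent first (ties broken alphabetically), smallest prefix reaching
# coverage 1 - eps; falls back to all admitted bases.
covering_code <- function(freq, eps, min_share) {
  bases <- c("A", "C", "G", "T")
  ord <- order(-freq, bases)
  admitted <- ord[freq[ord] >= min_share]
  if (!length(admitted)) admitted <- ord[1L]
  cum <- cumsum(freq[admitted])
  k <- which(cum >= 1 - eps)
  take <- if (length(k)) admitted[seq_len(k[1L])] else admitted
  set <- sort(bases[take])
  code <- names(Biostrings::IUPAC_CODE_MAP)[
    match(paste(set, collapse = ""), Biostrings::IUPAC_CODE_MAP)]
  if (is.na(code)) stop("no IUPAC code for base set ", paste(set, collapse = ""))
  code
}

base_freqs <- function(col) {
  tab <- table(factor(col, levels = c("A", "C", "G", "T")))
  as.numeric(tab) / max(1L, sum(tab))
}

# rows of the context matrix matching a pattern at given columns
rows_matching <- function(mat, cols, codes) {
  keep <- rep(TRUE, nrow(mat))
  for (j in seq_along(cols)) {
    allowed <- iupac_expand(codes[j])
    keep <- keep & mat[, cols[j]] %in% allowed
  }
  keep
}

#' Greedy discovery of degenerate methylated motifs from contexts
#'
#' Iteratively extracts one motif at a time from a pool of centred contexts.
#' Each round seeds a motif by repeatedly fixing the highest-information
#' flanking offset (information content >= `ic_min` bits) to its majority
#' base and restricting the pool, then generalises every fixed offset to the
#' minimal IUPAC code covering at least `1 - eps` of the contexts that match
#' the seed at the remaining fixed offsets (bases below `min_share` of the
#' column are treated as noise). Interior offsets that never reach `ic_min`
#' stay `N`, so bipartite spacer motifs arise naturally. The centre base is
#' forced to the majority of A/C; contexts matching the finished motif are
#' removed and the search repeats until no offset is informative or
#' `max_motifs` is reached. Deterministic given input order; ties fall to the
#' smaller offset magnitude (negative first), then alphabetical bases.
#'
#' @param contexts Character vector of `2 * flank + 1` contexts (see
#'   [extract_contexts()]).
#' @param flank Flank width used to build the contexts.
#' @param max_motifs Maximum number of motifs extracted.
#' @param ic_min Minimum information content (bits) for an offset to be fixed.
#' @param eps Allowed fraction of contexts not covered by a position's code.
#' @param min_sites Minimum pool size to keep searching.
#' @param min_share Minimum per-base column share for a base to enter a code.
#' @return List of `iupac_motif` (modification type from the centre base:
#'   A -> m6A, C -> m4C).
#' @export
discover_motifs <- function(contexts, flank = 10, max_motifs = 20,
                            ic_min = 0.5, eps = 0.05, min_sites = 20,
                            min_share = 0.15) {
  if (!length(contexts)) return(list())
  stopifnot(all(nchar(contexts) == 2 * flank + 1))
  mat <- do.call(rbind, strsplit(contexts, ""))
  centre <- flank + 1L
  offsets <- setdiff(seq_len(2L * flank + 1L), centre)
  motifs <- list()
  pool <- rep(TRUE, nrow(mat))

  while (length(motifs) < max_motifs && sum(pool) >= min_sites) {
    sub <- pool
    fixed_cols <- integer(0)
    fixed_base <- character(0)
    repeat {
      cand <- setdiff(offsets, fixed_cols)
      ics <- vapply(cand, function(j) ic_bits(base_freqs(mat[sub, j])), 0)
      ok <- which(ics >= ic_min)
      if (!length(ok)) break
      # highest IC; ties: smaller |offset|, negative side first
      rel <- cand[ok] - centre
      pick <- ok[order(-ics[ok], abs(rel), rel)][1L]
      j <- cand[pick]
      fr <- base_freqs(mat[sub, j])
      b <- c("A", "C", "G", "T")[order(-fr, c("A", "C", "G", "T"))][1L]
      sub2 <- sub & mat[, j] == b
      fixed_cols <- c(fixed_cols, j)
      fixed_base <- c(fixed_base, b)
      sub <- sub2
      if (sum(sub) < min_sites) break
    }
    if (!length(fixed_cols) || sum(sub) < 1L) break
    # centre base: majority of A/C over the seed subset
    nA <- sum(mat[sub, centre] == "A"); nC <- sum(mat[sub, centre] == "C")
    cB <- if (nC > nA) "C" else "A"
    # generalise each fixed offset over contexts matching the rest of the seed
    codes <- character(length(fixed_cols))
    for (k in seq_along(fixed_cols)) {
      others <- c(centre, fixed_cols[-k])
      other_codes <- c(cB, fixed_base[-k])
      rows <- pool & rows_matching(mat, others, other_codes)
      fr <- if (any(rows)) base_freqs(mat[rows, fixed_cols[k], drop = TRUE])
            else base_freqs(mat[sub, fixed_cols[k], drop = TRUE])
      codes[k] <- covering_code(fr, eps, min_share)
    }
    span <- range(c(fixed_cols, centre))
    pat <- rep("N", span[2] - span[1] + 1L)
    pat[fixed_cols - span[1] + 1L] <- codes
    pat[centre - span[1] + 1L] <- cB
    pattern <- paste(pat, collapse = "")
    meth_offset <- centre - span[1]
    mod_type <- if (cB == "A") "m6A" else "m4C"
    motif <- iupac_motif(pattern, meth_offset, mod_type)
    # remove contexts explained by the (degenerate) motif
    cols <- c(fixed_cols, centre)
    full_codes <- c(codes, cB)
    explained <- pool & rows_matching(mat, cols, full_codes)
    if (!any(explained)) break  # no progress; avoid looping
    pool <- pool & !explained
    motifs[[length(motifs) + 1L]] <- motif
  }
  motifs
}

#' Discover motifs for one genome from called sites
#'
#' Builds centred contexts from the called sites on the genome's contigs,
#' applying a stricter QV floor than the site caller (genome-wide scanning at
#' the caller's emission threshold admits too many chance contexts for clean
#' seeding), and runs [discover_motifs()].
#'
#' @param sites Called sites ([call_sites()]) restricted to one genome.
#' @param contigs Named character vector of the genome's contigs.
#' @param qv_floor Minimum QV for a site to contribute a context.
#' @param flank,... Passed to [extract_contexts()] / [discover_motifs()].
#' @return List of `iupac_motif`.
#' @export
discover_genome_motifs <- function(sites, contigs, qv_floor = 30, flank = 10, ...) {
  s <- sites[sites$qv >= qv_floor & sites$contig_id %in% names(contigs), , drop = FALSE]
  ctx <- extract_contexts(s, contigs, flank = flank)
  discover_motifs(ctx, flank = flank, ...)
}

#' Methylation ratio as reported in motif tables
#'
#' @param n_meth_sites,n_motif_sites Site counts.
#' @return `100 * n_meth_sites / n_motif_sites`, rounded to one decimal.
#' @export
methylation_ratio <- function(n_meth_sites, n_motif_sites) {
  stopifnot(all(n_motif_sites > 0), all(n_meth_sites >= 0),
            all(n_meth_sites <= n_motif_sites))
  round(100 * n_meth_sites / n_motif_sites, 1)
}

#' Summarise a motif over a genome's contigs
#'
#' Counts strand-specific occurrences across the contigs, the called sites
#' coinciding with occurrence methylation positions, the methylation ratio,
#' and means of QV and coverage over the contributing called sites. When the
#' kinetics table is supplied, the summary additionally reports the ratio over
#' *testable* occurrences (those whose site reached the caller's coverage
#' floor): with Poisson subread coverage a fixed fraction of occurrences is
#' never tested, so the plain ratio systematically understates the methylated
#' fraction, while the testable ratio is an unbiased estimate of it.
#'
#' @param motif An `iupac_motif`.
#' @param contigs Named character vector of contig sequences (one genome).
#' @param sites Called sites for the same contigs.
#' @param kinetics Optional kinetics table used to count testable occurrences.
#' @param min_cov_per_strand Coverage floor defining a testable occurrence.
#' @param genome_id Optional label.
#' @param in_reference Optional reference-known flag to record.
#' @return One-row `data.frame` mirroring the motif-table schema, plus
#'   `n_testable_sites` and `ratio_testable_pct` when kinetics are given.
#' @export
summarize_motif <- function(motif, contigs, sites, kinetics = NULL,
                            min_cov_per_strand = 25,
                            genome_id = NA_character_, in_reference = NA) {
  stopifnot(inherits(motif, "iupac_motif"))
  occ <- lapply(names(contigs), function(cid) {
    mp <- motif_meth_positions(motif, contigs[[cid]])
    if (nrow(mp)) cbind(contig_id = cid, mp) else NULL
  })
  occ <- do.call(rbind, occ)
  if (is.null(occ) || !nrow(occ)) stop("motif has no occurrences; cannot summarise")
  key <- function(d) paste(d$contig_id, d$position, d$strand)
  hit <- key(occ) %in% key(sites)
  called <- sites[key(sites) %in% key(occ), , drop = FALSE]
  out <- data.frame(genome_id = genome_id,
                    motif = motif$pattern,
                    meth_offset = motif$meth_offset,
                    mod_type = motif$mod_type,
                    in_reference = in_reference,
                    n_meth_sites = sum(hit),
                    n_motif_sites = nrow(occ),
                    ratio_pct = methylation_ratio(sum(hit), nrow(occ)),
                    mean_qv = if (nrow(called)) mean(called$qv) else NA_real_,
                    mean_subread_cov = if (nrow(called)) mean(called$coverage) else NA_real_,
                    stringsAsFactors = FALSE)
  if (!is.null(kinetics)) {
    kk <- kinetics[kinetics$coverage >= min_cov_per_strand, , drop = FALSE]
    n_testable <- sum(key(occ) %in% key(kk))
    out$n_testable_sites <- n_testable
    out$ratio_testable_pct <- if (n_testable > 0)
      methylation_ratio(min(sum(hit), n_testable), n_testable) else NA_real_
  }
  out
}

#' Occurrence and methylation-fraction filter for candidate motifs
#'
#' Drops candidates with fewer than `min_occurrences` motif occurrences or a
#' methylation ratio below `min_ratio_pct` in the genome; candidates sitting
#' exactly on either boundary are retained.
#'
#' @param summaries `data.frame` with `n_motif_sites` and `ratio_pct`.
#' @param min_occurrences Occurrence floor (strict `<` excludes).
#' @param min_ratio_pct Methylation-ratio floor in percent (strict `<`
#'   excludes).
#' @return The retained rows.
#' @export
filter_motifs <- function(summaries, min_occurrences = 50, min_ratio_pct = 1) {
  stopifnot(is.data.frame(summaries),
            all(c("n_motif_sites", "ratio_pct") %in% names(summaries)))
  keep <- summaries$n_motif_sites >= min_occurrences &
    summaries$ratio_pct >= min_ratio_pct
  summaries[keep, , drop = FALSE]
}
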