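#' Per-contig methylation profiles over a motif panel
#'
#' For every contig and every motif in the panel, the fraction of the motif's
#' strand-specific occurrences whose methylation position carries a called
#' modification. Entries backed by fewer than `min_occ` occurrences are
#' undefined (NA): short contigs cannot estimate a ratio reliably. When the
#' kinetics table is supplied, only *testable* occurrences (subread coverage
#' at or above the caller floor) enter the ratio and the `min_occ` rule, so
#' contigs from low-abundance genomes — which carry no usable kinetic signal —
#' yield undefined rather than spuriously unmethylated profiles.
#'
#' @param contigs Named character vector of contig sequences.
#' @param panel List of `iupac_motif` (the detected motif panel).
#' @param sites Called sites ([call_sites()]).
#' @param min_occ Minimum (testable) occurrences per contig for a defined
#'   entry.
#' @param kinetics Optional kinetics table defining testable occurrences.
#' @param min_cov_per_strand Coverage floor defining a testable occurrence.
#' @return Numeric matrix (contigs x motifs) of methylated fractions in
#'   `[0, 1]`, NA where undefined; motif patterns as column names.
#' @export
contig_profiles <- function(contigs, panel, sites, min_occ = 10,
                            kinetics = NULL, min_cov_per_strand = 25) {
  stopifnot(length(panel) >= 1)
  site_key <- paste(sites$contig_id, sites$position, sites$strand)
  test_key <- if (!is.null(kinetics)) {
    kk <- kinetics[kinetics$coverage >= min_cov_per_strand, , drop = FALSE]
    paste(kk$contig_id, kk$position, kk$strand)
  } else NULL
  P <- matrix(NA_real_, nrow = length(contigs), ncol = length(panel),
              dimnames = list(names(contigs),
                              vapply(panel, function(m) m$pattern, "")))
  for (j in seq_along(panel)) {
    for (cid in names(contigs)) {
      mp <- motif_meth_positions(panel[[j]], contigs[[cid]])
      if (!nrow(mp)) next
      keys <- paste(cid, mp$position, mp$strand)
      if (!is.null(test_key)) keys <- keys[keys %in% test_key]
      if (length(keys) < min_occ) next
      P[cid, j] <- mean(keys %in% site_key)
    }
  }
  P
}

# mean L1 distance over pairwise-defined entries; NA below the overlap floor
profile_distance <- function(x, y, min_shared = 3) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < min_shared) return(NA_real_)
  mean(abs(x[ok] - y[ok]))
}

#' Pairwise profile distance matrix
#'
#' @param profiles Matrix from [contig_profiles()].
#' @param min_shared Minimum shared defined entries for a defined distance.
#' @return Symmetric matrix with NA for undefined pairs.
#' @export
profile_distance_matrix <- function(profiles, min_shared = 3) {
  n <- nrow(profiles)
  D <- matrix(NA_real_, n, n, dimnames = list(rownames(profiles), rownames(profiles)))
  for (i in seq_len(n)) {
    D[i, i] <- 0
    for (j in seq_len(i - 1L)) {
      D[i, j] <- D[j, i] <- profile_distance(profiles[i, ], profiles[j, ],
                                             min_shared = min_shared)
    }
  }
  D
}

#' Methylation-profile congruence of a genome binning
#'
#' Mean silhouette of the contigs under their bin labels, using the L1
#' profile distance restricted to pairwise-defined entries. A score near 1
#' means contigs of a bin share a methylation pattern distinct from other
#' bins — epigenomic support for the binning; a score at or below 0 means the
#' methylation profiles carry no binning signal.
#'
#' @param profiles Matrix from [contig_profiles()].
#' @param bins Bin label per contig (same order as `profiles` rows).
#' @param min_shared Passed to [profile_distance_matrix()].
#' @return List with `score` (mean silhouette in `[-1, 1]`), `per_contig`
#'   silhouettes, and `n_used`.
#' @export
bin_congruence <- function(profiles, bins, min_shared = 3) {
  stopifnot(nrow(profiles) == length(bins))
  bins <- as.character(bins)
  tab <- table(bins)
  if (length(tab) < 2) stop("need at least 2 bins")
  if (any(tab < 2)) stop("need at least 2 contigs per bin")
  D <- profile_distance_matrix(profiles, min_shared = min_shared)
  n <- nrow(D)
  sil <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    own <- which(bins == bins[i]); own <- setdiff(own, i)
    a <- mean(D[i, own], na.rm = TRUE)
    bvals <- vapply(setdiff(names(tab), bins[i]), function(b) {
      mean(D[i, which(bins == b)], na.rm = TRUE)
    }, 0)
    bvals <- bvals[is.finite(bvals)]
    if (!is.finite(a) || !length(bvals)) next
    b <- min(bvals)
    m <- max(a, b)
    sil[i] <- if (m > 0) (b - a) / m else 0
  }
  if (all(is.na(sil))) stop("all profile distances undefined")
  list(score = mean(sil, na.rm = TRUE), per_contig = sil,
       n_used = sum(!is.na(sil)))
}
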