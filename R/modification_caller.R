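#' Phred-scaled modification QV for kinetic sites
#'
#' One-sided, one-sample location test of the mean log2 IPD ratio against 0:
#' `t = mean * sqrt(coverage) / max(sd, sd_floor)`, with the p-value from the
#' t distribution on `coverage - 1` degrees of freedom, reported as a
#' Phred-scaled score `-10 * log10(p)` capped at `qv_cap`. Vectorised.
#'
#' @param mean_ipd Mean log2 IPD ratio per site.
#' @param sd_ipd Per-site standard deviation (must be finite and >= 0).
#' @param coverage Subread count per site (must be >= 2).
#' @param sd_floor Lower bound on the standard deviation used in the
#'   statistic; guards against degenerate zero-variance sites.
#' @param qv_cap Upper bound on the reported QV.
#' @return Numeric vector of modification QVs.
#' @examples
#' site_qv(0, 1, 25)    # null-centred site: p = 0.5, QV ~ 3.01
#' site_qv(1.3, 1, 25)  # strong m6A-like signal
#' @export
site_qv <- function(mean_ipd, sd_ipd, coverage, sd_floor = 0.1, qv_cap = 1000) {
  n <- max(length(mean_ipd), length(sd_ipd), length(coverage))
  mean_ipd <- rep_len(mean_ipd, n)
  sd_ipd <- rep_len(sd_ipd, n)
  coverage <- rep_len(coverage, n)
  if (any(coverage < 2)) stop("QV undefined for coverage < 2")
  if (any(!is.finite(sd_ipd)) || any(sd_ipd < 0)) stop("invalid sd: must be finite and >= 0")
  tstat <- mean_ipd * sqrt(coverage) / pmax(sd_ipd, sd_floor)
  p <- stats::pt(tstat, df = coverage - 1, lower.tail = FALSE)
  pmin(-10 * log10(p), qv_cap)
}

#' Call modified sites from a kinetics table
#'
#' Emits every site meeting the per-strand coverage floor whose modification
#' QV reaches the threshold. The defaults follow the >25x-per-strand coverage
#' guidance for reliable single-molecule modification detection, with a QV
#' floor of 20 (p = 0.01), far below the mean QVs of confidently detected
#' motifs.
#'
#' @param kinetics `data.frame` with columns `contig_id`, `position`,
#'   `strand`, `coverage`, `mean_log2_ipd_ratio`, `sd_log2_ipd_ratio`.
#' @param min_cov_per_strand Minimum subread coverage for a site to be tested.
#' @param qv_min Minimum modification QV for a site to be emitted.
#' @param sd_floor,qv_cap Passed to [site_qv()].
#' @return `data.frame` of modified sites: `contig_id`, `position`, `strand`,
#'   `qv`, `coverage`, `effect` (mean log2 IPD ratio).
#' @export
call_sites <- function(kinetics, min_cov_per_strand = 25, qv_min = 20,
                       sd_floor = 0.1, qv_cap = 1000) {
  need <- c("contig_id", "position", "strand", "coverage",
            "mean_log2_ipd_ratio", "sd_log2_ipd_ratio")
  stopifnot(is.data.frame(kinetics), all(need %in% names(kinetics)))
  if (!nrow(kinetics)) {
    return(data.frame(contig_id = character(0), position = integer(0),
                      strand = character(0), qv = numeric(0),
                      coverage = integer(0), effect = numeric(0)))
  }
  k <- kinetics[kinetics$coverage >= min_cov_per_strand, , drop = FALSE]
  if (!nrow(k)) {
    return(data.frame(contig_id = character(0), position = integer(0),
                      strand = character(0), qv = numeric(0),
                      coverage = integer(0), effect = numeric(0)))
  }
  qv <- site_qv(k$mean_log2_ipd_ratio, k$sd_log2_ipd_ratio, k$coverage,
                sd_floor = sd_floor, qv_cap = qv_cap)
  keep <- qv >= qv_min
  out <- data.frame(contig_id = k$contig_id[keep], position = k$position[keep],
                    strand = k$strand[keep], qv = qv[keep],
                    coverage = k$coverage[keep],
                    effect = k$mean_log2_ipd_ratio[keep],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Write called sites as a BED-like browser track
#'
#' @param sites Result of [call_sites()].
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_sites_bed <- function(sites, path) {
  bed <- data.frame(chrom = sites$contig_id, start = sites$position,
                    end = sites$position + 1L,
                    name = sprintf("mod_qv%.0f", sites$qv),
                    score = pmin(1000L, as.integer(round(sites$qv))),
                    strand = sites$strand)
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
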