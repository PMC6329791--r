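#' Bundled reference table of detected methylated motifs
#'
#' Per-genome methylated motifs detected in a single-molecule metaepigenomic
#' survey of a freshwater lake microbial community: 29 motif rows across 10
#' draft genomes, with site and occurrence counts, methylation ratio, mean
#' modification QV, mean subread coverage, and whether the motif is an exact
#' match to a known recognition sequence in the restriction-enzyme reference
#' (REBASE).
#'
#' @return `data.frame` with columns `genome_id`, `motif`, `meth_offset`,
#'   `mod_type`, `in_rebase`, `n_meth_sites`, `n_motif_sites`, `ratio_pct`,
#'   `mean_qv`, `mean_subread_cov`.
#' @export
load_motif_table <- function() {
  path <- system.file("extdata", "freshwater_motifs.tsv", package = "metaepi",
                      mustWork = TRUE)
  read.delim(path, stringsAsFactors = FALSE)
}

#' Bundled reference table of restriction-modification system genes
#'
#' MTase (M), REase (R) and Type I specificity-subunit (S) genes annotated in
#' the same draft genomes, with the recognition motif and modification type of
#' the closest-match MTase, RM type, and the survey's own RM-system /
#' motif-detected conclusions for cross-checking. `gene_index` preserves the
#' relative gene order along each contig (locus-tag spacing), which the
#' RM-system neighborhood search uses. Motif `"?"` means unknown specificity;
#' `"Nonspecific"` marks an MTase whose closest homolog methylates without
#' sequence specificity; `meth_offset` is NA where the modified base is
#' undetermined.
#'
#' @return `data.frame`, one row per gene.
#' @export
load_gene_table <- function() {
  path <- system.file("extdata", "freshwater_rm_genes.tsv", package = "metaepi",
                      mustWork = TRUE)
  x <- read.delim(path, stringsAsFactors = FALSE, na.strings = "NA")
  x$mtase_name[is.na(x$mtase_name)] <- ""
  x$confirmed_motif[is.na(x$confirmed_motif)] <- ""
  x
}

#' Convert rows of a motif table to `iupac_motif` objects
#'
#' @param tab `data.frame` with columns `motif` (or `pattern`), `meth_offset`,
#'   `mod_type`.
#' @return List of `iupac_motif`.
#' @export
motifs_from_table <- function(tab) {
  pat <- if ("motif" %in% names(tab)) tab$motif else tab$pattern
  Map(iupac_motif, pat, tab$meth_offset, tab$mod_type)
}
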