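#' Assemble a pipeline run configuration
#'
#' Collects stage toggles, module parameters, paths and the seed controlling
#' every stochastic stage. With `use_fixtures = TRUE` the simulation stages
#' are skipped and the bundled reference tables are analysed instead
#' (motif-set reduction and MTase congruence only).
#'
#' @param out_dir Output directory for stage results.
#' @param seed Integer seed.
#' @param spec A [community_spec()] (ignored in fixture mode).
#' @param use_fixtures Analyse the bundled reference tables instead of a
#'   simulated community.
#' @param min_cov_per_strand,qv_min Caller thresholds.
#' @param qv_floor Discovery context QV floor.
#' @param flank,ic_min,eps,min_sites,min_share,max_motifs Discovery controls.
#' @param min_occurrences,min_ratio_pct Candidate filters.
#' @param min_occ_profile Per-contig occurrence floor for profile entries.
#' @param rm_window RM-system neighborhood window (gene indices).
#' @return List of class `run_config`.
#' @export
run_config <- function(out_dir, seed = 1L, spec = NULL, use_fixtures = FALSE,
                       min_cov_per_strand = 25, qv_min = 20, qv_floor = 30,
                       flank = 10, ic_min = 0.5, eps = 0.05, min_sites = 20,
                       min_share = 0.15, max_motifs = 20,
                       min_occurrences = 50, min_ratio_pct = 1,
                       min_occ_profile = 10, rm_window = 5) {
  if (is.null(spec)) spec <- community_spec(seed = seed)
  structure(list(out_dir = out_dir, seed = as.integer(seed), spec = spec,
                 use_fixtures = use_fixtures,
                 min_cov_per_strand = min_cov_per_strand, qv_min = qv_min,
                 qv_floor = qv_floor, flank = flank, ic_min = ic_min,
                 eps = eps, min_sites = min_sites, min_share = min_share,
                 max_motifs = max_motifs, min_occurrences = min_occurrences,
                 min_ratio_pct = min_ratio_pct,
                 min_occ_profile = min_occ_profile, rm_window = rm_window),
            class = "run_config")
}

config_as_list <- function(config) {
  x <- unclass(config)
  x$spec <- if (is.null(x$spec)) NULL else {
    s <- unclass(x$spec)
    s$systems <- lapply(s$systems, function(g) lapply(g, function(sys)
      list(motif = format_motif(sys$motif), mod_type = sys$motif$mod_type,
           fraction = sys$fraction)))
    s
  }
  x
}

write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the metaepigenomic inference pipeline
#'
#' Orchestrates generator -> caller -> motif discovery -> per-contig profiles
#' -> motif grouping, writing every stage product plus a summary JSON into
#' `config$out_dir`. In fixture mode the bundled motif and RM-gene tables are
#' analysed instead (deduplication/novelty and MTase congruence). Identical
#' configurations and seeds give byte-identical outputs.
#'
#' @param config A [run_config()].
#' @return Invisibly, the summary list (also written as `summary.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(config_as_list(config), file.path(config$out_dir, "config.yaml"))
  cfg_hash <- unname(tools::md5sum(file.path(config$out_dir, "config.yaml")))

  motif_tab <- load_motif_table()
  gene_tab <- load_gene_table()
  reference <- unique(motif_tab$motif[motif_tab$in_rebase == "Yes"])
  summary <- list(config_md5 = cfg_hash, seed = config$seed)

  if (config$use_fixtures) {
    grp <- dedupe_and_group(
      data.frame(genome_id = motif_tab$genome_id, pattern = motif_tab$motif,
                 meth_offset = motif_tab$meth_offset,
                 mod_type = motif_tab$mod_type, stringsAsFactors = FALSE),
      reference = reference)
    rep <- congruence_report(gene_tab, motif_tab, window = config$rm_window)
    write_tsv(grp$motifs, file.path(config$out_dir, "motif_groups.tsv"))
    write_tsv(rep$genes, file.path(config$out_dir, "congruence.tsv"))
    summary$n_motif_rows <- nrow(motif_tab)
    summary$n_distinct <- grp$n_distinct
    summary$n_novel_groups <- grp$n_novel_groups
    summary$congruence <- rep$tally
  } else {
    sim <- simulate_community(config$spec)
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(sim$genomes$contigs),
      file.path(config$out_dir, "contigs.fasta"))
    write_tsv(sim$kinetics, file.path(config$out_dir, "kinetics.tsv"))
    jsonlite::write_json(
      list(contig_map = sim$genomes$contig_map, sites = sim$truth$sites),
      file.path(config$out_dir, "truth.json"), dataframe = "columns")

    sites <- call_sites(sim$kinetics,
                        min_cov_per_strand = config$min_cov_per_strand,
                        qv_min = config$qv_min)
    write_tsv(sites, file.path(config$out_dir, "modified_sites.tsv"))
    write_sites_bed(sites, file.path(config$out_dir, "modified_sites.bed"))

    summaries <- list()
    recovered <- list()
    for (gid in unique(sim$genomes$contig_map$genome_id)) {
      cids <- sim$genomes$contig_map$contig_id[sim$genomes$contig_map$genome_id == gid]
      ctgs <- sim$genomes$contigs[cids]
      gsites <- sites[sites$contig_id %in% cids, , drop = FALSE]
      gkin <- sim$kinetics[sim$kinetics$contig_id %in% cids, , drop = FALSE]
      found <- discover_genome_motifs(gsites, ctgs, qv_floor = config$qv_floor,
                                      flank = config$flank,
                                      max_motifs = config$max_motifs,
                                      ic_min = config$ic_min, eps = config$eps,
                                      min_sites = config$min_sites,
                                      min_share = config$min_share)
      if (!length(found)) next
      sm <- do.call(rbind, lapply(found, summarize_motif, contigs = ctgs,
                                  sites = gsites, kinetics = gkin,
                                  min_cov_per_strand = config$min_cov_per_strand,
                                  genome_id = gid))
      sm <- filter_motifs(sm, min_occurrences = config$min_occurrences,
                          min_ratio_pct = config$min_ratio_pct)
      if (nrow(sm)) {
        summaries[[gid]] <- sm
        recovered[[gid]] <- found[match(sm$motif,
                                        vapply(found, function(m) m$pattern, ""))]
      }
    }
    motifs_out <- if (length(summaries)) do.call(rbind, summaries) else
      data.frame()
    write_tsv(motifs_out, file.path(config$out_dir, "motifs.tsv"))

    panel <- unlist(recovered, recursive = FALSE, use.names = FALSE)
    if (length(panel)) {
      seen <- !duplicated(vapply(panel, function(m) m$pattern, ""))
      panel <- panel[seen]
      P <- contig_profiles(sim$genomes$contigs, panel, sites,
                           min_occ = config$min_occ_profile,
                           kinetics = sim$kinetics,
                           min_cov_per_strand = config$min_cov_per_strand)
      write_tsv(data.frame(contig_id = rownames(P), P, check.names = FALSE),
                file.path(config$out_dir, "contig_profiles.tsv"))
      cong <- tryCatch(
        bin_congruence(P, sim$genomes$contig_map$genome_id),
        error = function(e) list(score = NA_real_, n_used = 0L))
      summary$bin_congruence <- cong$score
      grp <- dedupe_and_group(
        data.frame(genome_id = motifs_out$genome_id, pattern = motifs_out$motif,
                   meth_offset = motifs_out$meth_offset,
                   mod_type = motifs_out$mod_type, stringsAsFactors = FALSE),
        reference = reference)
      summary$n_distinct <- grp$n_distinct
      summary$n_novel_groups <- grp$n_novel_groups
    } else {
      summary$n_distinct <- 0L
      summary$n_novel_groups <- 0L
    }

    # truth-vs-called recovery report
    planted <- unlist(lapply(seq_along(config$spec$systems), function(g)
      vapply(config$spec$systems[[g]], function(s) s$motif$pattern, "")))
    found_pat <- if (nrow(motifs_out)) motifs_out$motif else character(0)
    summary$recovery <- list(
      planted = length(planted),
      recovered_exact = sum(planted %in% found_pat),
      spurious = sum(!found_pat %in% planted))
  }

  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}
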