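# helpers over the gene-table schema -----------------------------------------

is_fused_rm <- function(top_hit) grepl("^RM\\.", top_hit)

# exact pattern equality up to reverse complement
pattern_matches <- function(p, detected_patterns) {
  p %in% detected_patterns || rc_pattern(p) %in% detected_patterns
}

#' Congruence of one MTase record with the motifs detected in its genome
#'
#' An M-role record is congruent when the recognition motif of its
#' closest-match MTase exactly equals (up to reverse complement) a motif
#' detected in the same genome and the modification types agree. A record
#' whose closest-match motif is unknown (`"?"`) is unresolved; a
#' `"Nonspecific"` closest match is incongruent at this stage (it may be
#' rescued by orphan proposal).
#'
#' @param record One row of the gene table (role must be `M`).
#' @param detected `data.frame` of detected motifs for the same genome with
#'   columns `motif` (or `pattern`) and `mod_type`.
#' @return List: `gene_id`, `status` (`congruent` / `incongruent` /
#'   `unresolved`), `matched_motif` (NA unless congruent).
#' @export
congruence <- function(record, detected) {
  if (!identical(record$role, "M")) stop("congruence is defined for M-role records")
  pat <- if ("motif" %in% names(detected)) detected$motif else detected$pattern
  motif <- record$motif
  if (is.na(motif) || motif %in% c("?", "")) {
    return(list(gene_id = record$gene_id, status = "unresolved",
                matched_motif = NA_character_))
  }
  if (identical(motif, "Nonspecific")) {
    return(list(gene_id = record$gene_id, status = "incongruent",
                matched_motif = NA_character_))
  }
  idx <- which((pat == motif | pat == rc_pattern(motif)) &
                 detected$mod_type == record$mod_type)
  if (length(idx)) {
    list(gene_id = record$gene_id, status = "congruent",
         matched_motif = pat[idx[1L]])
  } else {
    list(gene_id = record$gene_id, status = "incongruent",
         matched_motif = NA_character_)
  }
}

#' Flag MTases that constitute restriction-modification systems
#'
#' An M-role gene is flagged when REase activity lies in its gene
#' neighborhood: an R-role gene within `window` gene indices on the same
#' contig, or a fused restriction-methylation top hit (`RM.` prefix) on the
#' gene itself. For Type I MTases a specificity-subunit (S) gene within the
#' window also counts, since Type I systems are M/S/R complexes.
#'
#' @param genes Gene table (see [load_gene_table()]).
#' @param window Maximum gene-index distance.
#' @return Logical vector along `genes` rows: TRUE/FALSE for M-role rows,
#'   NA for R/S rows.
#' @export
detect_rm_systems <- function(genes, window = 5) {
  n <- nrow(genes)
  out <- rep(NA, n)
  for (i in seq_len(n)) {
    if (genes$role[i] != "M") next
    same <- genes$contig_id == genes$contig_id[i]
    near <- same & abs(genes$gene_index - genes$gene_index[i]) <= window
    has_r <- any(near & genes$role == "R")
    has_s <- any(near & genes$role == "S")
    out[i] <- has_r || is_fused_rm(genes$top_hit[i]) ||
      (identical(genes$rm_type[i], "I") && has_s)
  }
  out
}

#' Propose specificities for orphan MTases and orphan motifs
#'
#' Within one genome, pairs each detected motif not explained by a congruent
#' MTase with an incongruent MTase of matching modification type (a
#' `"Nonspecific"` closest match is compatible with any type at this stage).
#' A pair is proposed when exactly one such MTase exists; with several
#' candidates, an MTase whose neighboring REase targets exactly the motif
#' wins; otherwise the motif stays unresolved. Motifs are processed in
#' alphabetical pattern order and each MTase is proposed at most once.
#'
#' @param genes Gene table rows of one genome.
#' @param statuses Character vector of congruence statuses along `genes` rows
#'   (NA for non-M rows).
#' @param detected Detected-motif table rows of the same genome.
#' @param window Neighborhood used for the REase-target tiebreak.
#' @return `data.frame` of proposals: `gene_id`, `motif`, `via` (either
#'   `"unique_type_match"` or `"rease_target"`).
#' @export
propose_orphans <- function(genes, statuses, detected, window = 5) {
  pat <- if ("motif" %in% names(detected)) detected$motif else detected$pattern
  explained <- vapply(seq_along(pat), function(i)
    any(statuses == "congruent" & !is.na(statuses) &
          vapply(seq_len(nrow(genes)), function(k) {
            genes$role[k] == "M" && !is.na(genes$motif[k]) &&
              !genes$motif[k] %in% c("?", "", "Nonspecific") &&
              (genes$motif[k] == pat[i] || rc_pattern(genes$motif[k]) == pat[i]) &&
              genes$mod_type[k] == detected$mod_type[i]
          }, TRUE)), TRUE)
  orphan_motifs <- order(pat)[!explained[order(pat)]]
  cand_rows <- which(genes$role == "M" & !is.na(statuses) & statuses == "incongruent")
  used <- logical(nrow(genes))
  props <- list()
  for (i in orphan_motifs) {
    cands <- cand_rows[!used[cand_rows] &
                         (genes$mod_type[cand_rows] == detected$mod_type[i] |
                            genes$motif[cand_rows] == "Nonspecific")]
    if (!length(cands)) next
    via <- "unique_type_match"
    if (length(cands) > 1L) {
      by_re <- cands[vapply(cands, function(k) {
        near <- genes$contig_id == genes$contig_id[k] & genes$role == "R" &
          abs(genes$gene_index - genes$gene_index[k]) <= window
        any(near & !is.na(genes$motif) &
              (genes$motif == pat[i] | genes$motif == rc_pattern(pat[i])))
      }, TRUE)]
      if (length(by_re) != 1L) next
      cands <- by_re
      via <- "rease_target"
    }
    used[cands] <- TRUE
    props[[length(props) + 1L]] <- data.frame(
      gene_id = genes$gene_id[cands], motif = pat[i], via = via,
      stringsAsFactors = FALSE)
  }
  if (length(props)) do.call(rbind, props) else
    data.frame(gene_id = character(0), motif = character(0), via = character(0))
}

#' Full congruence analysis of a gene table against detected motifs
#'
#' Runs [congruence()] on every M-role record, [detect_rm_systems()] over the
#' table, and [propose_orphans()] per genome; incongruent records with a
#' proposal become `proposed`.
#'
#' @param genes Gene table (all genomes).
#' @param motif_table Detected-motif table (all genomes) with `genome_id`,
#'   `motif`, `mod_type`.
#' @param window RM-system neighborhood window.
#' @return List: `genes` (input with `status`, `rm_system`,
#'   `proposed_motif` columns) and `tally`
#'   (`n_m`, `n_congruent`, `n_rm_systems`, `n_proposed`, `n_unresolved`).
#' @export
congruence_report <- function(genes, motif_table, window = 5) {
  statuses <- rep(NA_character_, nrow(genes))
  matched <- rep(NA_character_, nrow(genes))
  for (i in which(genes$role == "M")) {
    det <- motif_table[motif_table$genome_id == genes$genome_id[i], , drop = FALSE]
    res <- congruence(genes[i, ], det)
    statuses[i] <- res$status
    matched[i] <- res$matched_motif
  }
  rm_flags <- detect_rm_systems(genes, window = window)
  proposed <- rep(NA_character_, nrow(genes))
  for (gid in unique(genes$genome_id)) {
    gi <- which(genes$genome_id == gid)
    det <- motif_table[motif_table$genome_id == gid, , drop = FALSE]
    if (!nrow(det)) next
    pr <- propose_orphans(genes[gi, , drop = FALSE], statuses[gi], det,
                          window = window)
    if (nrow(pr)) {
      idx <- gi[match(pr$gene_id, genes$gene_id[gi])]
      proposed[idx] <- pr$motif
      statuses[idx] <- "proposed"
    }
  }
  out <- genes
  out$status <- statuses
  out$rm_system <- rm_flags
  out$proposed_motif <- proposed
  list(genes = out,
       tally = list(n_m = sum(genes$role == "M"),
                    n_congruent = sum(statuses == "congruent", na.rm = TRUE),
                    n_rm_systems = sum(rm_flags, na.rm = TRUE),
                    n_proposed = sum(statuses == "proposed", na.rm = TRUE),
                    n_unresolved = sum(statuses == "unresolved", na.rm = TRUE)))
}
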