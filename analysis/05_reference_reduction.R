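#!/usr/bin/env Rscript
# Stage 5: analysis of the bundled freshwater-survey tables. Deduplicates the
# 29 per-genome motif rows, marks motifs known to the restriction-enzyme
# reference, merges duplex partners and near-duplicates among the unknowns,
# and assigns MTase-motif congruence over the annotated RM genes.

suppressPackageStartupMessages(library(metaepi))

out <- "results/reference"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

motifs <- load_motif_table()
genes <- load_gene_table()

grouping <- dedupe_and_group(
  data.frame(genome_id = motifs$genome_id, pattern = motifs$motif,
             meth_offset = motifs$meth_offset, mod_type = motifs$mod_type),
  reference = unique(motifs$motif[motifs$in_rebase == "Yes"]))
write.table(grouping$motifs, file.path(out, "motif_groups.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("%d motif rows across %d genomes reduce to %d distinct motifs\n",
            nrow(motifs), length(unique(motifs$genome_id)), grouping$n_distinct))
cat(sprintf("%d motifs are unknown to the reference; they merge into %d novel groups:\n",
            sum(!grouping$motifs$reference_known), grouping$n_novel_groups))
for (g in grouping$groups) {
  cat(sprintf("  [%s] %s\n", g$kind, paste(g$patterns, collapse = " + ")))
}

report <- congruence_report(genes, motifs)
write.table(report$genes, file.path(out, "congruence.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
jsonlite::write_json(c(list(n_motif_rows = nrow(motifs),
                            n_distinct = grouping$n_distinct,
                            n_novel_groups = grouping$n_novel_groups),
                       report$tally),
                     file.path(out, "summary.json"),
                     auto_unbox = TRUE, digits = NA)

cat(sprintf("MTase congruence: %d of %d M-role genes match a detected motif\n",
            report$tally$n_congruent, report$tally$n_m))
cat(sprintf("%d MTases sit in RM systems; %d orphan MTases receive motif proposals:\n",
            report$tally$n_rm_systems, report$tally$n_proposed))
pr <- report$genes[!is.na(report$genes$proposed_motif), ]
for (i in seq_len(nrow(pr))) {
  cat(sprintf("  %s -> %s\n", pr$gene_id[i], pr$proposed_motif[i]))
}
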