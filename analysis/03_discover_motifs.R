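#!/usr/bin/env Rscript
# Stage 3: per-genome motif discovery. Each bin is processed independently:
# contexts around confidently called sites seed a greedy degenerate-motif
# search; candidates with <50 occurrences or <1% methylated fraction in the
# genome are excluded, as in the survey protocol.

suppressPackageStartupMessages(library(metaepi))

out <- "results/community"
contigs_set <- Biostrings::readDNAStringSet(file.path(out, "contigs.fasta"))
contigs <- setNames(as.character(contigs_set), names(contigs_set))
map <- read.delim(file.path(out, "contig_map.tsv"))
sites <- read.delim(file.path(out, "modified_sites.tsv"),
                    colClasses = c(strand = "character"))
kinetics <- read.delim(file.path(out, "kinetics.tsv"),
                       colClasses = c(strand = "character"))

rows <- list()
for (gid in unique(map$genome_id)) {
  cids <- map$contig_id[map$genome_id == gid]
  ctgs <- contigs[cids]
  gsites <- sites[sites$contig_id %in% cids, , drop = FALSE]
  gkin <- kinetics[kinetics$contig_id %in% cids, , drop = FALSE]
  found <- discover_genome_motifs(gsites, ctgs)
  if (!length(found)) {
    cat(sprintf("%s: no motif discovered (insufficient kinetic signal)\n", gid))
    next
  }
  sm <- do.call(rbind, lapply(found, summarize_motif, contigs = ctgs,
                              sites = gsites, kinetics = gkin, genome_id = gid))
  sm <- filter_motifs(sm)
  rows[[gid]] <- sm
  for (i in seq_len(nrow(sm))) {
    cat(sprintf("%s: %s (%s) ratio %.1f%% over %d occurrences, mean QV %.1f\n",
                gid, sm$motif[i], sm$mod_type[i], sm$ratio_pct[i],
                sm$n_motif_sites[i], sm$mean_qv[i]))
  }
}
motifs <- do.call(rbind, rows)
write.table(motifs, file.path(out, "motifs.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("%d motifs retained after the occurrence/fraction filters\n",
            if (is.null(motifs)) 0L else nrow(motifs)))
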