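#!/usr/bin/env Rscript
# Stage 2: per-site modification calling. A one-sided t test on the mean log2
# IPD ratio gives each site a Phred-scaled modification QV; sites with >=25
# subreads per strand and QV >= 20 are emitted.

suppressPackageStartupMessages(library(metaepi))

out <- "results/community"
kinetics <- read.delim(file.path(out, "kinetics.tsv"))
sites <- call_sites(kinetics)

write.table(sites, file.path(out, "modified_sites.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write_sites_bed(sites, file.path(out, "modified_sites.bed"))

n_testable <- sum(kinetics$coverage >= 25)
cat(sprintf("%d of %d sites reach the 25x coverage floor (%.1f%%)\n",
            n_testable, nrow(kinetics), 100 * n_testable / nrow(kinetics)))
cat(sprintf("%d modified sites called at QV >= 20 (%.2f%% of testable sites)\n",
            nrow(sites), 100 * nrow(sites) / n_testable))
truth <- jsonlite::read_json(file.path(out, "truth.json"), simplifyVector = TRUE)$sites
hit <- paste(truth$contig_id, truth$position, truth$strand) %in%
  paste(sites$contig_id, sites$position, sites$strand)
for (mt in unique(truth$mod_type)) {
  cat(sprintf("  per-site recall, %s: %.2f\n", mt, mean(hit[truth$mod_type == mt])))
}
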