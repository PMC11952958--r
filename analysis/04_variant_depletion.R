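#!/usr/bin/env Rscript
# Domain-level missense depletion: Vd/Vp for the planted 2x-depleted domain
# versus control intervals on the simulated 500-residue protein.
suppressMessages(library(saxlink))

dat <- "results/data"
vtab <- read.delim(file.path(dat, "variants.tsv"))
vs <- variant_set("SYN1", vtab$position, change = vtab$change,
                  flags = vtab$flags, protein_length = 500)
vs <- filter_variants(vs)  # no flagged variants planted; counts reported

doms <- domain_annotation(c("DZF", "linker", "dsRBDs"),
                          c(1, 151, 301), c(150, 300, 500), 500)
rows <- lapply(seq_len(nrow(doms)), function(i) {
  dr <- depletion_ratio(vs, doms[i, ], 500)
  data.frame(domain = doms$label[i], start = doms$start[i],
             end = doms$end[i], n_variants = dr$n_domain,
             vd = round(dr$v_d, 4), vp = round(dr$v_p, 4),
             ratio = round(dr$ratio, 3))
})
tab <- do.call(rbind, rows)
write.table(tab, "results/depletion_ratios.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
print(tab, row.names = FALSE)

combined <- combine_tracks(list(), vs, doms, protein_length = 500)
write.table(combined, "results/residue_table.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
cat("\nThe planted domain (residues 1-150, rate factor 0.5) shows Vd/Vp\n")
cat("well below 1, while undepleted intervals sit near or above 1 --\n")
cat("the signature used to flag functionally constrained domains.\n")
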