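#!/usr/bin/env Rscript
# Generate every synthetic dataset used by the downstream analyses, in the
# on-disk formats the loaders consume, with ground-truth records alongside.
suppressMessages(library(saxlink))

seed <- 1
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

# SEC-SAXS frame stack for a compact particle (sphere R = 50 A)
sec <- gen_sec_frames("sphere", list(R = 50), n_sample = 10, n_buffer = 10,
                      seed = sub_seed(seed, "sec"))
for (i in seq_along(sec$frames))
  write_saxs_curve(sec$frames[[i]], file.path(out, sprintf("frame_%02d.dat", i)))
jsonlite::write_json(sec$truth, file.path(out, "sec_truth.json"),
                     auto_unbox = TRUE, digits = NA)

# standalone curves: sphere, dumbbell, and a two-domain structure
for (spec in list(list(n = "sphere", s = "sphere", p = list(R = 50)),
                  list(n = "dumbbell", s = "dumbbell", p = list(R = 20, d = 80)))) {
  g <- gen_curve(spec$s, spec$p, noise_rel = 0.01, seed = sub_seed(seed, spec$n))
  write_saxs_curve(g$curve, file.path(out, paste0(spec$n, ".dat")))
  jsonlite::write_json(g$truth, file.path(out, paste0(spec$n, "_truth.json")),
                       auto_unbox = TRUE, digits = NA)
}
m2d <- make_fixture_structure("two_domain", n_res = 60, radius = 15,
                              seed = sub_seed(seed, "fix2d"))
write_structure(m2d, file.path(out, "two_domain.pdb"))
g2d <- gen_curve("structure", list(model = m2d), noise_rel = 0.01,
                 seed = sub_seed(seed, "curve2d"))
write_saxs_curve(g2d$curve, file.path(out, "two_domain.dat"))
jsonlite::write_json(g2d$truth, file.path(out, "two_domain_truth.json"),
                     auto_unbox = TRUE, digits = NA)

# two-condition cross-link table on a globular fixture, with planted
# RNA-enriched links (fold change 4) among null links
xl_model <- make_fixture_structure("cloud", n_res = 60, radius = 30,
                                   seed = sub_seed(seed, "xlfix"))
write_structure(xl_model, file.path(out, "xl_fixture.pdb"))
xl <- gen_crosslink_table(xl_model, n_true = 10, n_decoy = 10,
                          planted_fc = c(rep(4, 5), rep(1, 15)),
                          cv = 0.2, n_replicates = 3,
                          seed = sub_seed(seed, "xltab"),
                          path = file.path(out, "crosslinks.csv"))

# missense variants with a 2x-depleted domain on a 500-residue protein
doms <- data.frame(label = "DZF", start = 1, end = 150, factor = 0.5)
vt <- gen_variant_track(500, doms, baseline_rate = 0.2,
                        seed = sub_seed(seed, "variants"))
write.table(vt$variants, file.path(out, "variants.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)
jsonlite::write_json(vt$truth, file.path(out, "variants_truth.json"),
                     auto_unbox = TRUE, digits = NA)

# mass-photometry events for a protein/dsRNA titration
ev <- gen_mass_events(
  data.frame(n_protein = c(1, 1, 2, 3), n_rna = c(0, 1, 1, 1),
             fraction = c(0.3, 0.3, 0.2, 0.2)),
  m_protein = 110, m_rna = as.numeric(component_mass(rna_bp = 54)),
  sigma = 8, n = 4000, seed = sub_seed(seed, "mass"))
writeLines(format(ev$events, digits = 8), file.path(out, "mass_events.txt"))
jsonlite::write_json(ev$truth, file.path(out, "mass_truth.json"),
                     auto_unbox = TRUE, digits = NA)

# bead-on-string particle annotations
beads <- gen_bead_strings(n_strings = 50, beads_per_string = 5,
                          seed = sub_seed(seed, "beads"))
write.csv(beads$measurements, file.path(out, "bead_measurements.csv"),
          row.names = FALSE)
jsonlite::write_json(beads$truth, file.path(out, "beads_truth.json"),
                     auto_unbox = TRUE, digits = NA)

cat("Synthetic inputs written under", out, "\n")
cat(" - 20 SEC frames, 3 standalone curves, 2 fixture structures\n")
cat(" - crosslinks.csv:", nrow(xl$features), "features,",
    sum(xl$truth$planted_fc > 1), "planted RNA-enriched\n")
cat(" - variants.tsv:", nrow(vt$variants), "variants, domain factor 0.5\n")
cat(" - mass_events.txt:", length(ev$events), "events; beads:",
    nrow(beads$measurements), "beads\n")
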