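#!/usr/bin/env Rscript
# Generate the seeded synthetic configurations used by the downstream
# analyses: one spherical micelle per reported aggregation number for the
# three G2 systems, a G0-18C rod, a four-micelle siRNA complex, and a
# solvated micelle at 150 mM NaCl.
#
# Outputs: results/systems/

suppressMessages(library(dendrimicelle))
out <- "results/systems"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 2026

ref <- reference_micelles()
specs <- list(`G2-18C` = ad_spec(2, 18), `G2-15C` = ad_spec(2, 15),
              `G2-13C` = ad_spec(2, 13))
for (sys in names(specs)) {
  rows <- ref[ref$system == sys, ]
  for (i in seq_len(nrow(rows))) {
    fr <- generate_micelle(specs[[sys]], rows$n_ads[i],
                           core_radius_target = rows$core_radius[i],
                           d_tail = rows$tail_length[i] /
                             specs[[sys]]$n_tail_beads,
                           seed = seed + i)
    write_gro(fr, file.path(out, sprintf("%s_N%s.gro", sys,
                                         gsub("\\W", "_", rows$label[i]))))
  }
  cat(sys, ":", nrow(rows), "micelles generated\n")
}

rod <- generate_micelle(ad_spec(0, 18), 60, shape = "rod",
                        core_radius_target = 1.5, seed = seed)
write_gro(rod, file.path(out, "G0-18C_rod.gro"))
cat("G0-18C rod: 60 ADs, spherocylindrical core\n")

# four-micelle dendriplex: the bound configuration of the G2-18C system
cx <- generate_complex(
  lapply(c(13, 19, 24, 26), function(n)
    list(spec = ad_spec(2, 18), n_ads = n, core_radius = 1.1)),
  sirna_duplex_spec(), com_distances = c(3.6, 3.8, 3.9, 4.0), seed = seed)
write_gro(cx, file.path(out, "G2-18C_complex.gro"))
cat("complex: 82 ADs in 4 micelles around one siRNA\n")

solv <- solvate_and_neutralize(
  generate_micelle(ad_spec(2, 18), 13, core_radius_target = 1.0,
                   seed = seed, box = c(12, 12, 12)),
  nacl_mM = 150, seed = seed)
write_gro(solv, file.path(out, "G2-18C_N13_solvated.gro"))
tb <- table(solv$beads$molecule_kind)
cat(sprintf("solvated micelle: %d water, %d Na, %d Cl beads; total charge %d\n",
            tb[["water"]], tb[["Na"]], tb[["Cl"]],
            sum(solv$beads$charge)))
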