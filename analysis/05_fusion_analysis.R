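#!/usr/bin/env Rscript
# Micelle fusion dynamics on a scripted two-micelle trajectory: COM-distance
# plateaus, shared counterions and water, and the ordering of hydrophilic
# versus hydrophobic contact formation.
#
# Outputs: results/fusion/

suppressMessages(library(dendrimicelle))
out <- "results/fusion"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 2026

spec <- ad_spec(2, 18)
ma <- generate_micelle(spec, 13, core_radius_target = 1.0, seed = seed)
mb <- generate_micelle(spec, 13, core_radius_target = 1.0, seed = seed + 1)
tr <- generate_fusion_trajectory(ma, mb, n_frames = 60, seed = seed)
fu <- attr(tr, "fusion")

prof <- fusion_profile(tr, fu$members_a, fu$members_b)
write.csv(prof, file.path(out, "fusion_profile.csv"), row.names = FALSE)

pl <- find_plateaus(prof$time_ns, prof$com_distance)
write.csv(pl, file.path(out, "com_plateaus.csv"), row.names = FALSE)
cat("COM-distance plateaus (nm):\n")
print(round(pl, 2), row.names = FALSE)

first_cl <- prof$time_ns[which(prof$shared_chloride >= 3)[1]]
first_hyd <- prof$time_ns[which(prof$hydrophobic_contacts >= 3)[1]]
cat(sprintf("\nshared chloride network forms at %.0f ns, hydrophobic contact at %.0f ns\n",
            first_cl, first_hyd))
cat(sprintf("final frame: COM distance %.2f nm, %d shared Cl, %d hydrophobic contacts\n",
            prof$com_distance[60], prof$shared_chloride[60],
            prof$hydrophobic_contacts[60]))

trk <- track_aggregates(tr, 0.6)
write.csv(trk$table, file.path(out, "lineages.csv"), row.names = FALSE)
cat(sprintf("tracking: %d merge event(s) at t = %.0f ns\n",
            nrow(trk$merges), trk$merges$time_ns[1]))
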