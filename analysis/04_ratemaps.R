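#!/usr/bin/env Rscript
# Stage 4: spatial ratemaps for example cells.
#
# 3 cm occupancy-normalized ratemaps, Gaussian-smoothed (7 cm kernel) with
# masked renormalization, display-normalized to the pooled 95th percentile
# across the cell's three sessions. Writes the grids for the strongest
# increase cell as CSVs (rows = y bins).

library(envshift)

SEED <- 20260921 %% 2^31
g <- generate_triplet(sim_config(n_cells = 200, seed = SEED))
cls <- read.csv("results/02_classifications.csv")

inc <- cls[cls$label == "increase", ]
pick <- inc$cell_id[which.max(inc$delta)]
message("example increase cell: ", pick,
        sprintf(" (MFR %.2f -> %.2f -> %.2f spikes/s)",
                inc$mfr_pre[which.max(inc$delta)],
                inc$mfr_manip[which.max(inc$delta)],
                inc$mfr_post[which.max(inc$delta)]))

maps <- lapply(c(pre = "pre", manip = "manip", post = "post"), function(sn) {
  s <- g$triplet[[sn]]
  smooth_ratemap(compute_ratemap(s$spikes[[pick]], s$trace, s$arena))
})
nrm <- normalize_for_display(maps)
message(sprintf("display scale (pooled 95th percentile): %.2f spikes/s",
                attr(nrm, "scale")))

for (sn in names(maps)) {
  out <- sprintf("results/04_ratemap_%s_%s.csv", pick, sn)
  write.csv(round(nrm[[which(names(maps) == sn)]], 4), out,
            row.names = FALSE)
}
occw <- vapply(maps, function(m)
  sum(m$occupancy[m$visited]) , numeric(1))
message(sprintf("occupancy per session: %.1f / %.1f / %.1f s", occw[1],
                occw[2], occw[3]))
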