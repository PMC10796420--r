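#!/usr/bin/env Rscript
# Stage 3: histological metrics.
#
# Aggregates section-level biomarker percentages to per-animal region
# means, computes the plaque vulnerability index
# (%macrophage + %necrotic core) / (%SMC + %collagen), and tabulates the
# AHA lesion-type distribution per region and arm.

library(plaquemra)

out <- "results"
sections <- utils::read.csv(file.path(out, "histology.csv"))

agg <- aggregate_region_biomarkers(sections)
vi <- vulnerability_index(agg$pct_moma2, agg$pct_necrotic_core,
                          agg$pct_sma, agg$pct_collagen)
agg$vulnerability_index <- vi$index
utils::write.csv(agg, file.path(out, "region_metrics.csv"), row.names = FALSE)

aha <- do.call(rbind, lapply(c("none", "statin"), function(tr) {
  d <- aha_distribution(sections[sections$probe == "DT-MPIO", ],
                        treatment = tr)
  d$treatment <- tr
  d
}))
utils::write.csv(aha, file.path(out, "aha_distribution.csv"),
                 row.names = FALSE)

cat("Mean vulnerability index by region (dual-targeted arms):\n")
dt <- agg[agg$probe == "DT-MPIO", ]
print(round(with(dt, tapply(vulnerability_index,
                            list(region, treatment), mean)), 2))
cat("\nAHA type distribution, untreated arm (percent of sections):\n")
print(as.data.frame(aha[aha$treatment == "none", c("region", "aha_type",
                                                   "percent")]))
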