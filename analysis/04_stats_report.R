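#!/usr/bin/env Rscript
# Stage 4: statistical report.
#
# Inter-region Student's t-tests per arm and week (R4, the disease-free
# in-cuff zone, excluded), treated-vs-untreated tests per region and week,
# signal-biomarker correlations at the final imaging week, and tidy
# summary tables. A box-and-whisker figure of the signal by region and
# week is written alongside.

library(plaquemra)

out <- "results"
signals <- utils::read.csv(file.path(out, "signals.csv"))
sections <- utils::read.csv(file.path(out, "histology.csv"))

report <- longitudinal_report(signals, histology = sections)
write_report(report, file.path(out, "report"))

p <- plot_signal_by_region(signals)
ggplot2::ggsave(file.path(out, "report", "signal_by_region.pdf"), p,
                width = 8, height = 6)

print(report)

rt <- report$region_tests
nt <- rt[rt$probe == "DT-MPIO" & rt$treatment == "none", ]
cat("\nUntreated arm: significant region contrasts by week\n")
print(aggregate(significant ~ week, nt, sum))
st <- rt[rt$probe == "DT-MPIO" & rt$treatment == "statin", ]
cat("Statin arm: significant region contrasts (expect none):",
    sum(st$significant), "\n")
cat("\nSignal-biomarker correlations at the final week:\n")
print(as.data.frame(report$correlations))
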