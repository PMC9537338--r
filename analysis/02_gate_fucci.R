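#!/usr/bin/env Rscript
# Gate cells into FUCCI states from the two reporter channels and quantify
# state fractions on the venous vs arterial side of the latent axis.
# Expects results/data/ from 01_simulate.R.

library(avcycle)

truth <- read.delim("results/data/truth.tsv")
thr <- auto_thresholds(truth$mcherry[truth$state == "NEGATIVE"],
                       truth$mvenus[truth$state == "NEGATIVE"])
message(sprintf("auto thresholds (99th pct of negative control): mCherry %.1f, mVenus %.1f",
                thr$tau_red, thr$tau_green))

labels <- assign_fucci_state(truth$mcherry, truth$mvenus, thr)
agreement <- mean(as.character(labels) == truth$state)
message(sprintf("gated labels agree with simulator truth for %.1f%% of cells",
                100 * agreement))

side <- ifelse(truth$av_position >= 0, "arterial_side", "venous_side")
fractions <- state_fractions(labels, side)
print(fractions)

dir.create("results", showWarnings = FALSE)
write.table(data.frame(cell_id = truth$cell_id, label = labels),
            "results/labels.tsv", sep = "\t", quote = FALSE, row.names = FALSE)
write.table(fractions, "results/fractions.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

neg <- subset(fractions, state == "NEGATIVE")
message(sprintf("FUCCI-Negative: %.1f%% venous side vs %.1f%% arterial side",
                neg$percent[neg$group == "venous_side"],
                neg$percent[neg$group == "arterial_side"]))
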