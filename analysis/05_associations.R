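#!/usr/bin/env Rscript
# Association statistics: regress arterial, venous, TGF and BMP scores on the
# relative G1 score across cells; compare signaling scores between gated
# states (ANOVA + Tukey HSD); Welch t-test of the AV score between FUCCI
# states.

library(avcycle)

scores <- read.delim("results/scores.tsv")
labels <- read.delim("results/labels.tsv")
stopifnot(identical(scores$cell_id, labels$cell_id))

assoc <- associate_scores(scores, x = "relative_g1",
                          y = c("arterial_score", "venous_score",
                                "tgf_score", "bmp_score"))
print(assoc)
jsonlite::write_json(assoc, "results/associations.json", dataframe = "rows",
                     auto_unbox = TRUE, digits = NA)

message("\nTGF signaling score across gated FUCCI states (ANOVA + Tukey):")
print(anova_tukey(split(scores$tgf_score, labels$label)))

message("\nAV score, FUCCI-Red G1 vs FUCCI-Negative (Welch t):")
wt <- welch_t(scores$av_score[labels$label == "RED_G1"],
              scores$av_score[labels$label == "NEGATIVE"])
message(sprintf("t = %.2f (df %.1f), p = %.3g; mean AV: RED %.3f, NEG %.3f",
                wt$t, wt$df, wt$p, wt$mean_a, wt$mean_b))

dir_up <- assoc$slope[assoc$y == "arterial_score"] > 0 &&
  assoc$slope[assoc$y == "tgf_score"] > 0
dir_dn <- assoc$slope[assoc$y == "venous_score"] < 0 &&
  assoc$slope[assoc$y == "bmp_score"] < 0
message(sprintf("\ndirections: arterial/TGF rise with relative G1: %s; venous/BMP fall: %s",
                dir_up, dir_dn))
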