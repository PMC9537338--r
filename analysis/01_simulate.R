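#!/usr/bin/env Rscript
# Generate the synthetic study datasets: bulk RNA-seq of FACS-sorted FUCCI
# populations (3 states x 3 replicates) and droplet scRNA-seq of endothelial
# cells spread along a latent venous-to-arterial axis, with cell-cycle-state
# propensity coupled to the axis. Writes everything under results/data/.

library(avcycle)

out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(seed = 1)  # 2000 cells x 5000 genes, beta = 1.5, delta = 1
print(cfg)
panel <- make_gene_panel(cfg)
sc <- simulate_single_cells(cfg, panel)
bulk <- simulate_bulk_sorted(cfg, panel)

write_expression(sc$counts, file.path(out, "matrix.mtx"))
write.table(data.frame(cell_id = sc$cell_ids, av_position = sc$av_position,
                       state = sc$state, mcherry = sc$mcherry,
                       mvenus = sc$mvenus),
            file.path(out, "truth.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(data.frame(gene = rownames(bulk$counts), bulk$counts,
                       check.names = FALSE),
            file.path(out, "bulk_counts.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(data.frame(sample_id = colnames(bulk$counts),
                       state = bulk$sample_state, replicate = bulk$replicate),
            file.path(out, "bulk_samples.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
write_gmt(list(ARTERIAL = panel$arterial, VENOUS = panel$venous,
               TGF_SIGNALING = panel$tgf, BMP_SIGNALING = panel$bmp),
          file.path(out, "panels.gmt"))

message(sprintf("wrote %d cells x %d genes single-cell and %d bulk samples to %s",
                nrow(sc$counts), ncol(sc$counts), ncol(bulk$counts), out))
message("state composition: ",
        paste(sprintf("%s=%d", names(table(sc$state)), table(sc$state)),
              collapse = ", "))
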