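#!/usr/bin/env Rscript
# Group-level inference on the classified cohort: two-way type II ANOVA of
# resting potential over genotype x assigned type with Sidak-adjusted
# pairwise contrasts, plus the phospho-intensity normalization on a
# synthetic intensity table. Run 01 and 02 first.

suppressPackageStartupMessages(library(sgzephys))
seed <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(seed)) seed <- 1L

cells <- read_cell_table("results/cells_qc_passed.csv")
assign_tab <- read.csv("results/assignments.csv")
merged <- merge(cells[, c("cell_id", "vm")], assign_tab, by = "cell_id")

tab <- two_way_anova(merged$vm, merged$genotype, merged$assigned)
write.csv(tab, "results/vm_anova.csv", row.names = FALSE)
cat("two-way ANOVA of Vm (A = genotype, B = assigned type):\n")
print(tab, digits = 4)

# per-type genotype contrasts, Sidak-adjusted over the three comparisons
contrasts <- do.call(rbind, lapply(c("type1", "type2a", "type2b"), function(ty) {
  sub <- merged[merged$assigned == ty, ]
  tt <- t.test(vm ~ genotype, data = sub)
  data.frame(type = ty,
             mean_wt = mean(sub$vm[sub$genotype == "WT"]),
             mean_ko = mean(sub$vm[sub$genotype == "KO"]),
             p_value = tt$p.value)
}))
contrasts$p_adjusted <- sidak_adjust(contrasts$p_value, m = nrow(contrasts))
write.csv(contrasts, "results/vm_contrasts.csv", row.names = FALSE)
cat("\nper-type genotype contrasts on Vm (Sidak-adjusted):\n")
print(contrasts, digits = 4)

# phospho-signal normalization on synthetic intensity tables; the knockout
# table draws a brighter phospho channel
wt_tab <- generate_intensity_table(250, group = "WT", seed = seed + 3L)
ko_tab <- generate_intensity_table(250, f1_meanlog = log(180), group = "KO",
                                   seed = seed + 4L)
norm_wt <- normalize_phospho(wt_tab$f1, wt_tab$f2, wt_tab$area_nm2)
norm_ko <- normalize_phospho(ko_tab$f1, ko_tab$f2, ko_tab$area_nm2)
mw <- mann_whitney_u(norm_wt, norm_ko)
cat(sprintf("\nnormalized phospho intensity: WT median %.3g, KO median %.3g, %s p = %.3g\n",
            median(norm_wt), median(norm_ko), mw$method, mw$p_value))
write.csv(data.frame(group = c("WT", "KO"),
                     median_normalized = c(median(norm_wt), median(norm_ko)),
                     n = c(length(norm_wt), length(norm_ko))),
          "results/phospho_normalized.csv", row.names = FALSE)
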