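#!/usr/bin/env Rscript
# Step 6 — group-comparison statistics on the zone-distribution output.
#
# Two-way ANOVA (zone x group) with Bonferroni post hoc tests on the
# per-image zone fractions from step 2, plus a paired t test on the
# perinuclear fraction matched by repeat/image index — the test battery
# used with such distributions.

library(wpbquant)

per_image <- read.csv("results/zone_fractions_per_image.csv")
zcols <- c("perinuclear", "intermediate", "periphery")
long <- do.call(rbind, lapply(zcols, function(z) {
  data.frame(fraction = per_image[[z]], zone = z, group = per_image$group,
             repeat_id = per_image$repeat_id, image_id = per_image$image_id)
}))

res <- anova_bonferroni(long$fraction, long$zone, long$group)
print(res)

cl <- per_image[per_image$group == "clustered", ]
un <- per_image[per_image$group == "uniform", ]
ord <- function(d) d[order(d$repeat_id, d$image_id), ]
tt <- paired_t_test(ord(cl)$perinuclear, ord(un)$perinuclear)
cat(sprintf("\nPaired t, perinuclear clustered vs uniform: t = %.2f, df = %d, p = %.3g %s\n",
            tt$statistic, tt$df, tt$p_value, tt$tier))

stats_out <- rbind(
  data.frame(test = res$test, term = res$anova$term, statistic = res$anova$F,
             df = res$anova$df, p_value = res$anova$p_value, tier = res$anova$tier),
  data.frame(test = "paired_t", term = "perinuclear clustered vs uniform",
             statistic = tt$statistic, df = tt$df, p_value = tt$p_value,
             tier = tt$tier)
)
write.csv(stats_out, "results/statistics.csv", row.names = FALSE)
cat("Wrote results/statistics.csv\n")
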