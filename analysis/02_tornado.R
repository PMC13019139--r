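#!/usr/bin/env Rscript
# One-way deterministic sensitivity analysis: every model parameter is
# moved to the low and high end of its range (plus/minus 25%, PSA
# control explicitly 0.80-0.95) with all others at base, and the INMB of
# IMRT-20 versus RARP at 5,000,000 JPY/QALY is recorded -> tornado table.

suppressPackageStartupMessages(library(prostcea))

params <- default_parameters()
life_table <- generate_life_table()

ranges <- default_ranges(params)
torn <- one_way_dsa(params, ranges, params$settings$wtp, life_table)

dir.create("results", showWarnings = FALSE)
write_tornado(torn, "results/tornado.csv")

cat("tornado entries (sorted by INMB spread):\n")
print(torn[, c("path", "inmb_low", "inmb_high", "spread")], row.names = FALSE)
cat(sprintf("\nFindings: '%s' dominates the tornado (spread JPY %s);\n",
            torn$path[1], format(round(torn$spread[1]), big.mark = ",")))
cat(sprintf("INMB stays positive across every tested range: %s\n",
            all(pmin(torn$inmb_low, torn$inmb_high, na.rm = TRUE) > 0)))
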