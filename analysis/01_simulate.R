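#!/usr/bin/env Rscript
# Stage 1: simulate the two-site, six-species highland acoustic community
# and persist the annotation table for the downstream stages.
#
# The packaged example configuration emulates a passive-acoustic survey:
# hourly 5-min recording blocks over 7 study months at the high-altitude
# site and 6 at the low-altitude one (10 days per month), a dominant
# nocturnal high-frequency caller, a diurnal tonal species, two
# low-frequency Leptopelis-like species, a broadband generalist, and a
# rare nocturnal species, with rain suppression and daylight bird noise.

suppressPackageStartupMessages(library(anuraniche))

seed <- 1
dir.create("scratch", showWarnings = FALSE)
dir.create("results", showWarnings = FALSE)

cfg <- example_community_config(seed = seed)
records <- generate_dataset(cfg)
write_annotations(records, "scratch/annotations.csv")

n_minutes <- nrow(unique(records[, c("site", "date", "hour", "minute_index")]))
cat(sprintf("Simulated %d recorded minutes (%d annotation rows) at seed %d.\n",
            n_minutes, nrow(records), seed))

obs <- records[!is.na(records$species), ]
summary_tab <- aggregate(call_rate ~ site + species, data = obs, FUN = sum)
summary_tab$calling_minutes <- aggregate(call_rate ~ site + species, data = obs,
                                         FUN = length)$call_rate
summary_tab <- summary_tab[order(summary_tab$site, -summary_tab$call_rate), ]
names(summary_tab)[3] <- "total_calls"
write.csv(summary_tab, "results/01_simulation_summary.csv", row.names = FALSE)

cat("Total calls per site and species:\n")
print(summary_tab, row.names = FALSE)
cat("Community structure: the nocturnal high-frequency species dominates",
    "the call budget at the high site; at the low site the nocturnal",
    "chorus is led by the short-pulsed Leptopelis-like species and the",
    "diurnal tonal species reaches its higher daylight activity.\n")
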