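#!/usr/bin/env Rscript
# Stage 3: niche breadth, pairwise overlap and the randomization null.
#
# For each site: standardized inverse-Simpson niche breadth per species
# and dimension (call structure, diel, seasonal, additive total), the
# Schoener pairwise overlap matrix over total niches, and the comparison
# of the empirical overlap distribution against the null in which each
# overlap is the mean of 10 uniform(0,1) draws.

suppressPackageStartupMessages(library(anuraniche))

seed <- 1
cfg <- example_community_config(seed = seed)
design <- cfg$design
records <- read_annotations("scratch/annotations.csv", design)

breadth <- do.call(rbind, lapply(design$sites, function(s) {
  suppressWarnings(breadth_table(records, design, s))
}))
write.csv(breadth, "results/03_breadth.csv", row.names = FALSE)
cat("Standardized niche breadth (NB*) by dimension:\n")
print(breadth[breadth$dimension != "total",
              c("species", "site", "dimension", "nb_star")], row.names = FALSE)
cs <- breadth[breadth$dimension == "call_structure", ]
cat(sprintf("\nMean call-structure NB*: %s (equal 6-species partition would give %.2f).\n",
            paste(sprintf("%s %.2f", design$sites,
                          tapply(cs$nb_star, cs$site, mean)[design$sites]),
                  collapse = ", "),
            equal_partition_breadth(6)))

for (s in design$sites) {
  profs <- suppressWarnings(species_niche_profiles(records, design, s))
  totals <- Filter(Negate(is.null), lapply(profs, `[[`, "total"))
  om <- community_overlap_matrix(totals)
  write.csv(as.data.frame(om$values),
            sprintf("results/03_overlap_%s.csv", s))
  null <- random_overlap_null(n_pairs = om$n_pairs, n_draws = 10, reps = 667,
                              seed = seed + match(s, design$sites))
  cmp <- empiric_vs_random_test(om$values[upper.tri(om$values)], null)
  cat(sprintf("\n%s: NO_empiric = %.2f +/- %.2f over %d pairs; NO_random = %.2f +/- %.2f\n",
              s, om$mean, om$sd, om$n_pairs, null$mean, null$sd))
  cat(sprintf("  t = %.2f (p = %.2g), variance ratio F = %.2f (p = %.2g, larger: %s)\n",
              cmp$t, cmp$p_t, cmp$f, cmp$p_f, cmp$larger_variance))
  if (!exists("null_tab")) null_tab <- NULL
  null_tab <- rbind(null_tab, data.frame(
    site = s, empiric_mean = om$mean, empiric_sd = om$sd,
    null_mean = null$mean, null_sd = null$sd, t = cmp$t, p_t = cmp$p_t,
    f = cmp$f, p_f = cmp$p_f))
}
write.csv(null_tab, "results/03_overlap_null_comparison.csv", row.names = FALSE)

# partitioning is concentrated in the call-structure dimension
cs_means <- sapply(design$sites, function(s) {
  profs <- suppressWarnings(species_niche_profiles(records, design, s))
  cs <- Filter(function(p) !p$undefined, lapply(profs, `[[`, "call_structure"))
  community_overlap_matrix(cs)$mean
})
cat(sprintf("\nMean call-structure-only overlap: %s.\n",
            paste(sprintf("%s %.2f", design$sites, cs_means), collapse = ", ")))
cat("In this synthetic community the species partition the call-structure",
    "dimension strongly (overlap well below the 0.5 null mean), while the",
    "shared nocturnal and seasonal timing keeps the combined total-niche",
    "overlap near the null mean.\n")
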