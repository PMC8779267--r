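#!/usr/bin/env Rscript

# Stage 5: Monte-Carlo parasitoid yield.  Two parameterizations are run:
#   (a) "fitted"  -- link-scale means/SEs taken from the models fitted to the
#       synthetic September tables in stages 3-4;
#   (b) "preset"  -- link-scale means/SEs taken directly from the reported
#       coefficient tables (the package's built-in calibration).
# Each cell's yield is eggs x emergence probability, 2000 draws.

library(parayield)

seed <- 20170926  # date of the second field collection
n_draws <- 2000L

tabs <- read_event_tables("results/data")
if (is.null(tabs$containers)) stop("run analysis/01_simulate.R first")
dir.create("results/tables", recursive = TRUE, showWarnings = FALSE)
dir.create("results/figures", recursive = TRUE, showWarnings = FALSE)

# (a) fitted route
cs <- count_sample(tabs$containers, collection = "september")
hfit <- fit_hurdle_nb(cs)
cells <- setdiff(unique(cs$cells), parayield:::all_zero_cells(cs))
egg_emm <- emm_counts(hfit, cells, type = "conditional")
pfit <- fit_weighted_logit(binomial_sample(tabs$clutches,
                                           "parasitoid_emergence"))
prop_emm <- emm_props(pfit)
inputs_fit <- treatment_distributions(egg_emm, prop_emm)
cat("Excluded cells (fitted route):\n")
print(attr(inputs_fit, "excluded"), row.names = FALSE)
dr_fit <- simulate_yield(inputs_fit, n_draws, seed = child_seed(seed, "yield"))
su_fit <- summarize_yield(dr_fit)
cat("\nYield from the fitted models:\n")
print(su_fit)

# (b) preset route
inputs_pre <- yield_preset()
dr_pre <- simulate_yield(inputs_pre, n_draws,
                         seed = child_seed(seed, "yield") + 1L)
su_pre <- summarize_yield(dr_pre)
cat("\nYield from the reported estimates:\n")
print(su_pre)

both <- rbind(cbind(route = "fitted", as.data.frame(su_fit)),
              cbind(route = "preset", as.data.frame(su_pre)))
write.csv(both, "results/tables/yield_summary.csv", row.names = FALSE)
ytab <- data.frame(route = "preset",
                   cell = rep(colnames(dr_pre), each = nrow(dr_pre)),
                   draw = rep(seq_len(nrow(dr_pre)), ncol(dr_pre)),
                   yield = as.vector(dr_pre))
write.csv(ytab, "results/tables/yield_draws.csv", row.names = FALSE)

png("results/figures/yield_boxplot.png", width = 900, height = 600)
par(mar = c(9, 4, 2, 1))
plot(dr_pre, main = "Simulated parasitoid yield (preset route)")
dev.off()
cat("\nWrote results/tables/{yield_summary,yield_draws}.csv and",
    "results/figures/yield_boxplot.png\n")
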