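#!/usr/bin/env Rscript
# Stage 1: simulate the study inputs — a scored food composition table
# spanning the five colour classes within food groups, and a cohort of
# 2000 adults with three 24-h records each (two weekday, one weekend),
# three latent dietary profiles and a planted fraction of energy
# under-reporters.

suppressPackageStartupMessages({
  library(cnlsim)
  library(dplyr)
})

seed <- 2026
outdir <- "results/data"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

foods <- generate_food_table(n_foods = 200, seed = seed)
cat("food table:", nrow(foods), "foods in",
    length(unique(foods$group_id)), "groups\n")
print(table(foods$colour))

pop <- generate_population(2000, foods, seed = seed + 1)
cat("population:", nrow(pop$persons), "persons,",
    nrow(pop$records), "consumption events,",
    sum(pop$truth$under_reporter), "planted under-reporters\n")

write_cnl_table(foods, file.path(outdir, "foods.csv"))
write_cnl_table(pop$persons, file.path(outdir, "persons.csv"))
write_cnl_table(pop$records, file.path(outdir, "records.csv"))
write_cnl_table(pop$truth, file.path(outdir, "truth.csv"))
cat("wrote", outdir, "\n")
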