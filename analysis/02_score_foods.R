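#!/usr/bin/env Rscript
# Stage 2: score the food table with the modified FSA model and allocate
# 5-CNL colour classes. The synthetic table arrives scored; re-scoring
# from the raw composition columns here doubles as an end-to-end check
# and produces the per-group class census used to sanity-check the
# substitution pools.

suppressPackageStartupMessages({
  library(cnlsim)
  library(dplyr)
})

foods <- read_cnl_table("results/data/foods.csv")
raw <- foods[, setdiff(names(foods),
                       c("a_points", "c_points_applied", "protein_counted",
                         "fsa_score", "colour"))]
scored <- score_foods(raw)
stopifnot(all(scored$fsa_score == foods$fsa_score),
          all(scored$colour == foods$colour))
cat("re-scored", nrow(scored), "foods; scores span",
    min(scored$fsa_score), "to", max(scored$fsa_score), "\n")

census <- scored |>
  count(group_id, colour) |>
  tidyr::pivot_wider(names_from = colour, values_from = n, values_fill = 0)
print(as.data.frame(census))

rng <- enumerate_score_range()
cat("brute-forced score range over", rng$n_combinations,
    "point combinations:", rng$min, "to", rng$max, "\n")

dir.create("results", showWarnings = FALSE)
write_cnl_table(scored, "results/foods_scored.csv")
write_cnl_table(census, "results/class_census.csv")
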