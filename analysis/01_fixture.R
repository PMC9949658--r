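#!/usr/bin/env Rscript
# Materialize the packaged Argentina 2020 input set as a directory of CSV
# tables and confirm it round-trips through the reader unchanged.

suppressPackageStartupMessages(library(ssbcra))

out_dir <- "results/fixture"
fx <- ssb_fixture()
write_fixture(out_dir, fx)
back <- read_inputs(out_dir)
stopifnot(isTRUE(all.equal(lapply(fx, as.data.frame),
                           lapply(back, as.data.frame))))

s <- summarize_inputs(fx)
cat("Wrote", length(list.files(out_dir)), "input tables to", out_dir, "\n")
cat(sprintf("Adults:   %.1fM, band-weighted SSB intake %.2f servings/day\n",
            s$population[s$segment == "adult"] / 1e6,
            s$mean_servings[s$segment == "adult"]))
cat(sprintf("Children: %.1fM, band-weighted SSB intake %.2f servings/day\n",
            s$population[s$segment == "child"] / 1e6,
            s$mean_servings[s$segment == "child"]))
cat("Round-trip read reproduced every table field-for-field.\n")
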