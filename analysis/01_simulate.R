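#!/usr/bin/env Rscript
# Stage 1: simulate the gas-production experiment.
#
# Emulates the study design — 4 silage treatments (0/10/20/30 % dehydrated
# cashew pseudo-fruit) whose kinetic truths are the published per-treatment
# Richards equations, 6 sample flasks per treatment, 3 blanks, readings
# every 5 minutes for 24 h, noise sd 0.1 mL/100 mg DM — and writes the raw
# long-format table that the later stages ingest.

suppressPackageStartupMessages(library(rumengas))

cfg <- experiment_config(seed = 20251203)
raw <- generate_experiment(cfg)

dir.create("results", showWarnings = FALSE)
write_gas_table(raw, "results/gas_raw.csv")
jsonlite::write_json(
  list(seed = cfg$seed, n_flasks_per_treatment = cfg$n_flasks_per_treatment,
       n_blanks = cfg$n_blanks, sampling_interval_min = cfg$sampling_interval,
       duration_h = cfg$duration, noise_sd = cfg$noise_sd,
       mass_mg = cfg$mass_mg,
       treatments = lapply(cfg$treatments, function(tr)
         list(label = tr$label, model = tr$model_id,
              params = as.list(tr$params)))),
  "results/gas_raw_provenance.json", auto_unbox = TRUE, digits = NA)

cat(sprintf("simulated %d flasks (%d blank) x %d readings -> results/gas_raw.csv\n",
            length(unique(raw$flask)), sum(raw$is_blank) / 289,
            length(unique(raw$time_h))))
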