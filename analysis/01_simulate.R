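#!/usr/bin/env Rscript
# Step 1: simulate a disease/health urinary-peptidome study with planted
# ground truth, and write every artefact in the package's exchange formats.
# Downstream steps (02-05) read only these files.

suppressPackageStartupMessages(library(urodegradome))

seed <- 20210531
out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- synthetic_config()
study <- generate_study(cfg, seed = seed)
print(study)

write_proteome(study$proteome, file.path(out, "proteome.fasta"))
write_specificity_rules(study$rules, file.path(out, "protease_rules.tsv"))
write_association_table(study$disease, file.path(out, "disease_peptides.tsv"))
write_association_table(study$health, file.path(out, "health_peptides.tsv"))
write_manifest(study$manifest, file.path(out, "ground_truth.json"))

rep <- validate_against_proteome(study$disease, study$proteome)
print(rep)
stopifnot(rep$n_mismatch == 0, rep$n_missing == 0)
message("simulated study written to ", out)
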