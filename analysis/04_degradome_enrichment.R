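#!/usr/bin/env Rscript
# Step 4: peptide-centric protease prediction at both termini, the health
# reference library, and per-condition enrichment with Bonferroni control.

suppressPackageStartupMessages(library(urodegradome))

data_dir <- "results/data"
out <- "results"
disease <- load_association_table(file.path(data_dir, "disease_peptides.tsv"))
health <- load_association_table(file.path(data_dir, "health_peptides.tsv"))
prot <- read_proteome(file.path(data_dir, "proteome.fasta"))
rules <- read_specificity_rules(file.path(data_dir, "protease_rules.tsv"))

dp <- predict_degradome(disease, rules, prot, grouping = "condition")
hp <- predict_degradome(health, rules, prot, grouping = "all")
print(dp); print(hp)
write_predictions(dp, file.path(out, "disease_predictions.tsv"))

ref <- build_reference(hp)
print(ref)
er <- enrich(dp, ref, alpha = 0.05, rules = rules)
write_enrichment(er, file.path(out, "protease_enrichment.tsv"))

sig <- er[er$significant, ]
message(nrow(sig), " significant (condition, protease) enrichments of m = ",
        attr(er, "m"), " tests; ", sum(er$disease_only),
        " protease(s) predicted only in disease")
print(head(sig[, c("group", "protease_id", "k", "n", "K", "N",
                   "fold_enrichment", "p_adj")], 10))

# recovery check against the planted ground truth
truth <- jsonlite::read_json(file.path(data_dir, "ground_truth.json"))
hit <- vapply(names(truth$planted_proteases), function(cc) {
  pl <- unlist(truth$planted_proteases[[cc]])
  mean(pl %in% sig$protease_id[sig$group == cc])
}, numeric(1))
message("planted-protease recovery per condition: ",
        paste(sprintf("%s=%.0f%%", names(hit), 100 * hit), collapse = ", "))
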