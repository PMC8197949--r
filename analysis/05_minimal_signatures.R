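#!/usr/bin/env Rscript
# Step 5: minimal degradome signatures - the smallest sets of significantly
# enriched proteases that identify each condition uniquely.

suppressPackageStartupMessages(library(urodegradome))

data_dir <- "results/data"
out <- "results"
disease <- load_association_table(file.path(data_dir, "disease_peptides.tsv"))
health <- load_association_table(file.path(data_dir, "health_peptides.tsv"))
prot <- read_proteome(file.path(data_dir, "proteome.fasta"))
rules <- read_specificity_rules(file.path(data_dir, "protease_rules.tsv"))

dp <- predict_degradome(disease, rules, prot, grouping = "condition")
hp <- predict_degradome(health, rules, prot, grouping = "all")
er <- enrich(dp, build_reference(hp), rules = rules)
mat <- significance_matrix(er)

classes <- disease$condition_class
tab <- minimal_signature_table(mat, kmax = 3, classes = classes)
write.table(tab, file.path(out, "minimal_degradome_signatures.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
print(tab)
message(sum(!is.na(tab$k_star)), " of ", nrow(tab),
        " conditions have a unique degradome signature (kmax = 3)")
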