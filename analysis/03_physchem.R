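#!/usr/bin/env Rscript
# Step 3: physicochemical descriptor profiles of the per-class signature
# peptides against the health reference (length, mass, pI, GRAVY, proline).

suppressPackageStartupMessages(library(urodegradome))

data_dir <- "results/data"
out <- "results"
disease <- load_association_table(file.path(data_dir, "disease_peptides.tsv"))
health <- load_association_table(file.path(data_dir, "health_peptides.tsv"))

sig <- extract_signatures(build_network(disease))
peps <- signature_class_peptides(sig, disease, health)

panel <- descriptor_panel(unique(peps$sequence))
write.table(panel, file.path(out, "descriptor_panel.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cd <- class_distributions(peps, min_peptides = 20)
write.table(cd$summary, file.path(out, "class_descriptor_summary.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(cd$density, file.path(out, "class_descriptor_density.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

print(cd$summary[cd$summary$descriptor == "length", ])
message("descriptor summaries written for ",
        length(unique(cd$summary$class)), " classes (",
        paste(cd$excluded, collapse = ", "),
        if (length(cd$excluded)) " excluded below the 20-peptide threshold" else "")
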