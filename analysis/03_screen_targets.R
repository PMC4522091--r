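#!/usr/bin/env Rscript
# Candidate screen: locate every NAD(H)/NADP(H)-dependent reaction, then
# exclude no-flux, essential, orphan, spontaneous, blocklisted-subsystem,
# boundary and objective reactions.  Survivors get their applicable
# manipulation modes (swap / knockout / overexpression) from the net
# direction of cofactor turnover at the reference.

library(redoxscreen)
dir.create("results", showWarnings = FALSE)

model <- read_model("results/model.json")
cof <- toy_cofactor_spec()
ref <- reference_state(model)

located <- find_cofactor_reactions(model, cof)
cat("located", length(located), "cofactor-coupled reactions:",
    paste(located, collapse = ", "), "\n")

cs <- filter_candidates(model, ref, cof)
cat(nrow(cs$candidates), "candidates survive the filters:\n")
print(cs$candidates, row.names = FALSE)
cat("excluded:", paste(names(cs$excluded), "(", cs$excluded, ")"), "\n")

write_candidates_tsv(cs, "results/candidates.tsv")
cat("wrote results/candidates.tsv\n")
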