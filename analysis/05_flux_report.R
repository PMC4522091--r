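#!/usr/bin/env Rscript
# Flux maps and cofactor share sheets.  Fluxes are expressed in molar
# percent of the glucose uptake rate; cofactor consumption is decomposed
# into per-reaction shares, with the fermentative recycling share
# (lactate + ethanol branches) and the transhydrogenase couplings reported
# for the reference state and for the top-ranked perturbation.

library(redoxscreen)
dir.create("results", showWarnings = FALSE)

model <- read_model("results/model.json")
cof <- toy_cofactor_spec()
ref <- reference_state(model)

fm <- flux_percentages(ref, model, "EX_glc_e")
write_flux_map_tsv(fm, "results/flux_map_reference.tsv")

sh <- cofactor_shares(ref, model, cof, recycling_set = c("LDH", "ADHE"),
                      transhydrogenase_id = "THD")
cat(sprintf("reference: %.1f%% of NADH recycled through lactate/ethanol;\n",
            sh$nadh$recycling_percent))
cat(sprintf("  transhydrogenase carries %.1f%% of NADPH production, draining %.1f%% of NADH\n",
            sh$nadph$thd_production_percent, sh$nadh$thd_consumption_percent))

summary <- jsonlite::read_json("results/campaign_summary.json")
if (summary$mode == "cofactor_swap") {
  pm <- build_swap(model, summary$top_target, summary$factor, ref, cof)
  st <- moma(pm, ref)
  fm2 <- flux_percentages(st, pm, "EX_glc_e")
  write_flux_map_tsv(fm2, "results/flux_map_top_perturbation.tsv")
  sh2 <- cofactor_shares(st, pm, cof, recycling_set = c("LDH", "ADHE"),
                         transhydrogenase_id = "THD")
  cat(sprintf("after %s swap: NADH recycling share %.1f%%, transhydrogenase NADPH share %.1f%%\n",
              summary$top_target, sh2$nadh$recycling_percent,
              sh2$nadph$thd_production_percent))
}

shares_tab <- rbind(
  data.frame(cofactor = "nadh", reaction = names(sh$nadh$consumer_percent),
             consumer_percent = unname(sh$nadh$consumer_percent)),
  data.frame(cofactor = "nadph", reaction = names(sh$nadph$consumer_percent),
             consumer_percent = unname(sh$nadph$consumer_percent)))
write.table(shares_tab, "results/cofactor_shares.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("wrote results/flux_map_reference.tsv, results/cofactor_shares.tsv\n")
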