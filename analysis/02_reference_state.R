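#!/usr/bin/env Rscript
# Reference flux state of the producer strain model: FBA maximizing growth
# under the microaerobic uptake constraints, disambiguated by minimal total
# flux.  Writes the flux table and the NADH/NADPH flux-sum balance sheets --
# the redox imbalance that motivates the target screen.

library(redoxscreen)
dir.create("results", showWarnings = FALSE)

model <- read_model("results/model.json")
ref <- reference_state(model)
stopifnot(ref$status == "optimal")

cat(sprintf("reference growth: %.4f 1/h-equivalent\n", ref$objective_value))
cat(sprintf("isobutanol secretion: %.3f mmol/gDCW/h\n", ref$fluxes[["EX_iboh_e"]]))
cat(sprintf("byproducts (lac/etoh/succ): %.3f / %.3f / %.3f\n",
            ref$fluxes[["EX_lac_e"]], ref$fluxes[["EX_etoh_e"]],
            ref$fluxes[["EX_succ_e"]]))

nadh <- flux_sum(ref, model, "nadh")
nadph <- flux_sum(ref, model, "nadph")
cat(sprintf("NADH flux-sum %.2f vs NADPH flux-sum %.2f (%.1f-fold): excess NADH, scarce NADPH\n",
            nadh$total_production, nadph$total_production,
            nadh$total_production / nadph$total_production))

write.table(data.frame(id = names(ref$fluxes), flux = unname(ref$fluxes)),
            "results/reference_fluxes.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
balances <- do.call(rbind, lapply(list(nadh, nadph), function(fs) {
  rbind(data.frame(metabolite = fs$metabolite_id, reaction = names(fs$producers),
                   role = "producer", flux = unname(fs$producers)),
        data.frame(metabolite = fs$metabolite_id, reaction = names(fs$consumers),
                   role = "consumer", flux = unname(fs$consumers)))
}))
write.table(balances, "results/cofactor_balances.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("wrote results/reference_fluxes.tsv, results/cofactor_balances.tsv\n")
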