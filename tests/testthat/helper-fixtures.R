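# Small builders shared across the suite.

simple_pri <- function(id = "P1", stage = "upstream", conc = 10,
                       codes = "medium_toxicity", ...) {
  pri_record(id, paste0("impurity ", id), stage, conc, codes, ...)
}

simple_ctx <- function(...) {
  dose_context(product_dose = 500, product_protein_concentration = 50,
               body_weight = 50, ...)
}

# A three-record well-formed inventory
small_inventory <- function() {
  list(pri_record("P1", "sodium chloride", "downstream_pre_CEX", 9000, "GRAS"),
       pri_record("P2", "arginine", "formulation", 2000, "approved_excipient"),
       simple_pri("P3", conc = 25))
}
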