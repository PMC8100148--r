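.datatable.aware <- TRUE

# silence R CMD check notes for data.table non-standard evaluation columns
utils::globalVariables(c(
  "embryo_id", "cell_id", "gene_id", "chromosome", "position", "ref", "alt",
  "state", "pooled_ref", "pooled_alt", "N", "start", "end", "."
))
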