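.datatable.aware <- TRUE

utils::globalVariables(c(
  ".key", ".SD", "count", "cdr3_nt", "v_gene", "j_gene",
  "nt_variant_count"
))
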