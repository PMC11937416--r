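.datatable.aware <- TRUE

# silence R CMD check notes for data.table's non-standard evaluation symbols
utils::globalVariables(c(".N", ".SD", "genotype"))
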