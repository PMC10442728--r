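# data.table is used via :: throughout; declare awareness so `[` dispatch
# uses data.table semantics inside this namespace.
.datatable.aware <- TRUE
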