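{"n_rows":3,"n_cols":3,"doors_ew":[[true,true],[false,true],[true,true]],"doors_ns":[[true,true,true],[true,false,true]]}
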