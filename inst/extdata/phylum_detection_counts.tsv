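pool	n_detected	n_datasets
soil	9814	10250
nonsoil	18027	47953
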