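class	soil_occurrence_pct	n_genera	group
Terriglobia	92.61	209	SPL
Vicinamibacteria	85.61	70	SPL
Thermoanaerobaculia	78.84	50	SPL
Blastocatellia	76.2	52	SPL
Polarisedimenticolia	33.47	19	moderate
UBA6911	29.48	19	moderate
Holophagae	24	17	NSPL
HRBIN11	15.78	3	moderate
Aminicenantia	11.5	34	NSPL
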