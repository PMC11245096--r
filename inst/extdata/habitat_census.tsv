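habitat	n_datasets
soil	10250
engineered	16320
freshwater	11408
host-associated	165152
marine	13880
non-marine saline and alkaline	1306
terrestrial non-soil	5039
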