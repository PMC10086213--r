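patient	sts_type	volume_ml	tre_per_volume_mm_per_ml
1	MFS	165.0	0.013
2	UPS	510.5	0.005
3	LMS	215.9	0.009
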