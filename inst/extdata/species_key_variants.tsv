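id	base	variants	expected_verdict
Ptr_T2R10	hT2R10		binder
Ggo_T2R10	hT2R10		binder
Nle_T2R10	hT2R10		binder
Mmu_T2R10	hT2R10		binder
Ppy_T2R10	hT2R10		binder
Pha_T2R10	hT2R10		binder
Clu_T2R10	hT2R10		binder
Lpi_T2R10	hT2R10		binder
Vfe_T2R10	hT2R10		binder
Vco_T2R10	hT2R10		binder
Vvu_T2R10	hT2R10		binder
Cbr_T2R10	hT2R10		binder
Vze_T2R10	hT2R10		binder
Ame_T2R10	hT2R10		binder
Ssc_T2R10	hT2R10	3.37=H;5.39=S	non_binder
Bta_T2R10	hT2R10	3.33=I;5.43=F	non_binder
Oar_T2R10	hT2R10	3.33=I;5.40=H;7.39=I;7.42=R	non_binder
Cja_T2R10	hT2R10	3.33=I;7.39=I;7.42=S	uncertain
Ggo_T2R46	hT2R46	3.36=S	reduced_binder
Ppa_T2R46	hT2R46	6.63=K	reduced_binder
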