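id	expected_verdict
hT2R10	binder
N94	binder
N93	binder
N83	binder
N82	binder
N81	uncertain
N80	non_binder
hT2R46	binder
N34	reduced_binder
N24	reduced_binder
N23	reduced_binder
N2	non_binder
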