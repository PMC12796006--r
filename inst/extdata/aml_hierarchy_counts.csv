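state,n_cells
primitive_like,5039
GMP_like,6432
erythroid_like,1816
lymphoid_like,55
committed_like,2825
AML_total,16167
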