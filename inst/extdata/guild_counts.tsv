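woodland	species	count
gamlingay	N_vespilloides	1811
gamlingay	other_Nicrophorus	408
waresley	N_vespilloides	1963
waresley	other_Nicrophorus	133
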