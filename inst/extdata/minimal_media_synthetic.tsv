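# SYNTHETIC illustrative minimal-media table for the toy network shipped
# with this package. Format: one row per medium component; `observed_mu`
# repeats the synthetic reference growth rate (1/h) for the medium.
# These are NOT literature measurements.
medium	exchange_id	uptake	observed_mu
glucose_ammonium	EX_carbon	10	1.00
glucose_ammonium	EX_salt	10	1.00
glucose_valine	EX_carbon	7.5	0.75
glucose_valine	EX_salt	10	0.75
glycerol_ammonium	EX_carbon	5	0.50
glycerol_ammonium	EX_salt	10	0.50
glycerol_valine	EX_carbon	2.5	0.25
glycerol_valine	EX_salt	10	0.25
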