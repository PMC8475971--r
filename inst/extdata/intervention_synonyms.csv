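raw_string,canonical_string
anti sars cov 2 convalescent plasma,convalescent plasma
convalescent covid 19 plasma,convalescent plasma
hcq,hydroxychloroquine
covid 19 convalescent plasma,convalescent plasma
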