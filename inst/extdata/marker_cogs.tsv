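cog_id
COG5501
COG5502
COG5503
COG5504
COG5505
COG5506
COG5507
COG5508
COG5509
COG5510
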