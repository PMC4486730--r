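animal_id	injected_g	mass_kg
seal_01	5	403
seal_02	5	410
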