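quantity,value
hr_total,48
hr_affected,38
pa_within_hr_km2,1354
pa_within_hr_burned_km2,1054
pa_within_hr_burned_brazil_km2,970
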