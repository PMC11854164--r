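factor,value,unit,yield_pct
enzyme_pct,4.5,%,24.21
enzyme_pct,1.5,%,17.72
pH,5,,20.57
temperature_C,50,C,23.15
temperature_C,60,C,23.16
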