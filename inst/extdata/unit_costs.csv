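specimen,consumables,collection_overhead,lab_analysis
plasma,0.31,0.87,17.22
dbs,0.92,0.47,17.54
psc,5.00,0.47,17.54
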