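key,specimen,platform,sensitivity,specificity,sens_low,sens_high,spec_low,spec_high
plasma_capctm,plasma,capctm,0.983,0.994,0.967,0.993,0.983,0.999
psc_capctm,psc,capctm,0.91,0.99,0.84,0.96,0.98,1
psc_cobas8800,psc,cobas8800,0.970,0.972,0.924,0.992,0.949,0.986
dbs_capctm,dbs,capctm,0.948,0.939,0.846,0.984,0.720,0.989
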