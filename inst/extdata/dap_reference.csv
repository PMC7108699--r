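protocol,mean_mGy_cm2,sd_mGy_cm2,n
CS9300 facial,215.1,0.4,2
CS9300 dual jaw,91.0,0.4,2
RAYSCAN alpha+ large jaw,176.6,0.4,2
RAYSCAN alpha+ jaw,167.9,0.6,2
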