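wavelength_nm,extinction
440,115000
450,63000
460,44000
470,33000
480,27000
490,24000
500,21000
510,20000
520,25000
530,39500
540,53200
550,43500
560,32600
570,44900
580,50100
590,14000
600,3200
610,1000
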