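wavelength_nm,extinction
440,480000
450,103000
460,72000
470,55000
480,45000
490,39000
500,33000
510,29000
520,28000
530,30000
540,46600
550,53200
560,53600
570,49000
580,37000
590,18000
600,14700
610,10000
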