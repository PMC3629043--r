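wavelength_nm,extinction
440,120000
450,134000
460,128000
470,110000
480,85000
490,52000
500,25000
510,9000
520,3000
530,1000
540,400
550,150
560,60
570,30
580,15
590,8
600,4
610,2
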