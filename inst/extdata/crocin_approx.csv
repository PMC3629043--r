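wavelength_nm,extinction
440,89000
450,82000
460,72000
470,50000
480,30000
490,15000
500,6500
510,2500
520,900
530,300
540,100
550,40
560,15
570,8
580,4
590,2
600,1
610,1
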