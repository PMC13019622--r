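 &FCI NORB=1,NELEC=2,MS2=0,
  ORBSYM=1,
  ISYM=1,
 &END
 1.0557129400212608E+00    1    1    1    1
-1.9317484483177290E+00    1    1    0    0
 0.0000000000000000E+00    0    0    0    0
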