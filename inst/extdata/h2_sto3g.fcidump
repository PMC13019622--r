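 &FCI NORB=2,NELEC=2,MS2=0,
  ORBSYM=1,1,
  ISYM=1,
 &END
 6.7459408575489610E-01    1    1    1    1
 1.8125791414359010E-01    2    1    2    1
 6.6356399013596412E-01    2    2    1    1
 6.9749534330824969E-01    2    2    2    2
-1.2527970626081892E+00    1    1    0    0
-4.7560230553503785E-01    2    2    0    0
 7.1428571428571430E-01    0    0    0    0
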