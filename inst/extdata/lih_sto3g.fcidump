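 &FCI NORB=6,NELEC=4,MS2=0,
  ORBSYM=1,1,1,1,1,1,
  ISYM=1,
 &END
 1.6585529512019592E+00    1    1    1    1
-1.1191930029733375E-01    2    1    1    1
 1.3391231308703835E-02    2    1    2    1
 3.6725278339235157E-01    2    2    1    1
 6.2538163651192843E-03    2    2    2    1
 4.8762523275433162E-01    2    2    2    2
-1.3853591541674495E-01    3    1    1    1
 1.1228979600738107E-02    3    1    2    1
-1.5920266220815965E-02    3    1    2    2
 2.1656266460575856E-02    3    1    3    1
 1.3355945369204430E-02    3    2    1    1
-3.3618969313392315E-03    3    2    2    1
-4.8502867916345879E-02    3    2    2    2
 1.7895245866486625E-04    3    2    3    1
 1.3018637204632104E-02    3    2    3    2
 3.9565196986667200E-01    3    3    1    1
-1.1061908707050367E-02    3    3    2    1
 2.2373958373770680E-01    3    3    2    2
 1.8324361491191810E-03    3    3    3    1
 7.4243831331383932E-03    3    3    3    2
 3.3793002010969303E-01    3    3    3    3
 9.8179326309002172E-03    4    1    4    1
 7.4921366372978637E-03    4    2    4    1
 2.3447533005916302E-02    4    2    4    2
 1.0256951299523287E-02    4    3    4    1
 1.9273006018850552E-02    4    3    4    2
 4.1277681254551404E-02    4    3    4    3
 3.9631891492297300E-01    4    4    1    1
-4.3658228622977004E-03    4    4    2    1
 2.7039496789111256E-01    4    4    2    2
-4.9738882527633936E-03    4    4    3    1
 5.7180107985836852E-03    4    4    3    2
 2.8200256336103002E-01    4    4    3    3
 3.1294545407006846E-01    4    4    4    4
 9.8179326309002189E-03    5    1    5    1
 7.4921366372978646E-03    5    2    5    1
 2.3447533005916309E-02    5    2    5    2
 1.0256951299523288E-02    5    3    5    1
 1.9273006018850559E-02    5    3    5    2
 4.1277681254551425E-02    5    3    5    3
 1.6869135772219358E-02    5    4    5    4
 3.9631891492297305E-01    5    5    1    1
-4.3658228622977082E-03    5    5    2    1
 2.7039496789111256E-01    5    5    2    2
-4.9738882527633954E-03    5    5    3    1
 5.7180107985837000E-03    5    5    3    2
 2.8200256336103002E-01    5    5    3    3
 2.7920718252562982E-01    5    5    4    4
 3.1294545407006852E-01    5    5    5    5
 5.2676617046501138E-02    6    1    1    1
-8.8810673292418190E-03    6    1    2    1
-6.8079845504413700E-03    6    1    2    2
-2.3131298082968081E-03    6    1    3    1
 1.6717047247082422E-03    6    1    3    2
 1.0411436050840245E-02    6    1    3    3
 5.7476450657549354E-04    6    1    4    4
 5.7476450657549364E-04    6    1    5    5
 8.4971826554318050E-03    6    1    6    1
-4.0969035046438514E-02    6    2    1    1
 4.7366714285559299E-03    6    2    2    1
 1.2702808257044906E-01    6    2    2    2
 5.0705800454403779E-04    6    2    3    1
-3.4546566220337166E-02    6    2    3    2
-1.2296605267894034E-02    6    2    3    3
-1.6060904904925660E-02    6    2    4    4
-1.6060904904925663E-02    6    2    5    5
 1.2675757429983788E-04    6    2    6    1
 1.2387738287071895E-01    6    2    6    2
 1.7647800739883080E-02    6    3    1    1
-3.6905306903815510E-03    6    3    2    1
-5.1343201788649255E-02    6    3    2    2
 4.4003916757624599E-03    6    3    3    1
 9.3622323615091298E-03    6    3    3    2
 3.5981677399476296E-02    6    3    3    3
 2.1986168642108075E-03    6    3    4    4
 2.1986168642108080E-03    6    3    5    5
 4.3025576926944489E-03    6    3    6    1
-3.1861379678886574E-02    6    3    6    2
 2.6437742256673329E-02    6    3    6    3
-6.1085909241676275E-03    6    4    4    1
-1.9574773336934637E-02    6    4    4    2
-1.3731266183742326E-02    6    4    4    3
 1.9714295413985901E-02    6    4    6    4
-6.1085909241676293E-03    6    5    5    1
-1.9574773336934637E-02    6    5    5    2
-1.3731266183742328E-02    6    5    5    3
 1.9714295413985904E-02    6    5    6    5
 3.6174172805359911E-01    6    6    1    1
 3.3125173030687754E-03    6    6    2    1
 4.5402347892084838E-01    6    6    2    2
-1.1337291868219768E-02    6    6    3    1
-4.3299666730066307E-02    6    6    3    2
 2.4146477211334869E-01    6    6    3    3
 2.6818805620632602E-01    6    6    4    4
 2.6818805620632602E-01    6    6    5    5
-3.0318568145823589E-03    6    6    6    1
 1.3449844693865623E-01    6    6    6    2
-4.4054561020934038E-02    6    6    6    3
 4.5394257764839679E-01    6    6    6    6
-4.7283245705716013E+00    1    1    0    0
 1.0566548393233705E-01    2    1    0    0
-1.4943959377044780E+00    2    2    0    0
 1.6701455092727757E-01    3    1    0    0
 3.3019956775908160E-02    3    2    0    0
-1.1258514445959242E+00    3    3    0    0
-1.1362235834525474E+00    4    4    0    0
-1.1362235834525478E+00    5    5    0    0
-3.4323976516882772E-02    6    1    0    0
-5.3971079807738249E-02    6    2    0    0
 3.0531106069366005E-02    6    3    0    0
-9.5018500679370066E-01    6    6    0    0
 9.9502487562189046E-01    0    0    0    0
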