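{"model":"mamyo","revision":"1.0.0","state":{"V":-84.6418086508145,"cal_C2":0.900699130723068,"cal_C1":4.17501573998151e-06,"cal_O":0.000697638238089791,"cal_I1Ca":0.025600712310556,"cal_I2Ca":0.0523620639633605,"cal_I1V":0.0076256213275732,"cal_I2V":0.0130106583719943,"ito_C3":0.978219286384435,"ito_C2":0.00109193466972692,"ito_C1":2.67169813394189e-06,"ito_O":1.51146500719282e-06,"ito_I":0.000372726882772202,"ito_IS1":0.00474047792628558,"ito_IS2":0.0155713909729262,"kur_C4":0.742263852953614,"kur_C3":0.218325060430693,"kur_C2":0.0241359284660744,"kur_C1":0.00122746243161505,"kur_O":5.60897812765582e-05,"kur_I":0.0139916059385727,"kr_C3":0.928303615658022,"kr_C2":0.0669488198314378,"kr_C1":0.00438877407964292,"kr_O":0.000355210396132447,"kr_I":3.58003506562375e-06,"ryr_R":0.245913330387471,"ryr_O":1.75706382171923e-07,"ryr_I":5.38798428413372e-07,"ryr_RI":0.7540859551058,"m":0.0098652464733204,"h":0.983640728144716,"j":0.989705705253437,"mL":0.0098652464733204,"hL":0.245292668124523,"x_ss":0.00345243045761443,"Na_i":14.677500335413,"K_i":135.895390723907,"Cl_i":7.78969288852224,"Ca_i":0.000103366319232585,"Ca_sl":0.000119791539849878,"Ca_j":0.000358290250776385,"Ca_sr":0.613225053228644,"TnCL":0.0103750720548259,"CaM":0.000349430148475442,"SRB":0.00251743189185449,"SLLsl":0.000341632207030274,"SLHsl":0.00386547328465838,"SLLj":0.0147785136830314,"SLHj":0.110718588042126,"Csqn":1.60196488956488,"ck_j":0.020316684540462,"ck_sl":0.0201342976816958,"ck_cyt":0.00838571428031426,"Ph_PLB":0.0168604883334676}}
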