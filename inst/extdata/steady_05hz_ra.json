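{"model":"mamyo","revision":"1.0.0","state":{"V":-84.7622770790586,"cal_C2":0.999814387384394,"cal_C1":4.2714715517263e-06,"cal_O":1.03165165919098e-05,"cal_I1Ca":1.221577502515e-05,"cal_I2Ca":2.22340026939089e-05,"cal_I1V":4.79107973659858e-05,"cal_I2V":8.86640210405663e-05,"ito_C3":0.997267288324787,"ito_C2":0.00109506027046161,"ito_C1":5.60373723099869e-07,"ito_O":1.0650880146916e-07,"ito_I":2.63076375382418e-05,"ito_IS1":0.000339004510780219,"ito_IS2":0.00127167237481856,"kur_C4":0.752817673317904,"kur_C3":0.219428450979717,"kur_C2":0.0239941548105678,"kur_C1":0.0011735826777925,"kur_O":2.74089768383669e-05,"kur_I":0.00255872923905723,"kr_C3":0.929184234028687,"kr_C2":0.0661833593388168,"kr_C1":0.00428650763302131,"kr_O":0.000342478636732583,"kr_I":3.42036429391875e-06,"ryr_R":0.664357325098878,"ryr_O":1.8538318498493e-08,"ryr_I":9.36581874933937e-09,"ryr_RI":0.335642646995235,"m":0.0096777754185626,"h":0.984082710279288,"j":0.989994241342844,"mL":0.0096777754185626,"hL":0.263290021946064,"x_ss":0.00233131885740002,"Na_i":13.4645660360357,"K_i":137.005789632795,"Cl_i":7.69208164389932,"Ca_i":0.000104723252647337,"Ca_sl":0.000108458547116631,"Ca_j":0.000165143748808132,"Ca_sr":0.637723902023964,"TnCL":0.0104112517292253,"CaM":0.000353759032525012,"SRB":0.00254109938865303,"SLLsl":0.000309445419732733,"SLHsl":0.00355818273406115,"SLLj":0.00689924750581607,"SLHj":0.0710157299567929,"Csqn":1.63427026081311,"ck_j":0.00343163103556938,"ck_sl":0.00436304107039834,"ck_cyt":0.00665478119561442,"Ph_PLB":0.0143514288426297}}
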