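"device_id","name","description","comparator","real_price","real_price_currency","has_cea","gain","outcome_kind","surv1y_a","surv1y_b","cost_b","cost_b_currency","othercosts_a","othercosts_a_currency","time_horizon_months","source","source_kind","reported_vbp_eur"
"D1","Neovasc Reducer","coronary sinus reducer stent","before-after comparison in included patients",6500,"EUR",TRUE,0.138,"QALY",,,6988,"EUR",8702,"EUR","12","Gallone 2020","CEA_registry",6578
"D2","Ascyrus Medical Dissection Stent (AMDS)","hybrid aortic system for dissections","standard of care",13000,"EUR",TRUE,,"life_year",0.804,0.756,0,"EUR",0,"EUR","12","Bozso 2021; Pape 2015","HTA_report",2880
"D3","Cardioband","tricuspid valve reconstruction system","standard of care",22000,"EUR",TRUE,,"life_year",0.36,0.23,0,"EUR",0,"EUR","12","Taramasso 2019","HTA_report",7800
"D4","Pascal Mitral Ace","mitral valve transcatheter repair system","standard of care",22000,"EUR",TRUE,1.07,"QALY",,,10704,"GBP",26471,"GBP","lifetime","Shore 2021","HTA_report",45272
"D5","Cardia Ultrasept Dia","atrial septal defect closure device","surgical closure",4243,"EUR",TRUE,0.03,"QALY",,,16000,"BRL",6836,"BRL","lifetime","Costa 2014","CEA_registry",3579
"D6","Synthetic placeholder device 06","synthetic placeholder; no usable CEA in the appraisal record","",5200,"EUR",FALSE,,,,,,,,,,"",,
"D7","Synthetic placeholder device 07","synthetic placeholder; no usable CEA in the appraisal record","",18500,"EUR",FALSE,,,,,,,,,,"",,
"D8","Synthetic placeholder device 08","synthetic placeholder; no usable CEA in the appraisal record","",3100,"EUR",FALSE,,,,,,,,,,"",,
"D9","Synthetic placeholder device 09","synthetic placeholder; no usable CEA in the appraisal record","",9800,"EUR",FALSE,,,,,,,,,,"",,
"D10","Synthetic placeholder device 10","synthetic placeholder; no usable CEA in the appraisal record","",27500,"EUR",FALSE,,,,,,,,,,"",,
"D11","Synthetic placeholder device 11","synthetic placeholder; no usable CEA in the appraisal record","",1450,"EUR",FALSE,,,,,,,,,,"",,
"D12","Synthetic placeholder device 12","synthetic placeholder; no usable CEA in the appraisal record","",7600,"EUR",FALSE,,,,,,,,,,"",,
"D13","Synthetic placeholder device 13","synthetic placeholder; no usable CEA in the appraisal record","",12200,"EUR",FALSE,,,,,,,,,,"",,
"D14","Synthetic placeholder device 14","synthetic placeholder; no usable CEA in the appraisal record","",33000,"EUR",FALSE,,,,,,,,,,"",,
"D15","Synthetic placeholder device 15","synthetic placeholder; no usable CEA in the appraisal record","",2400,"EUR",FALSE,,,,,,,,,,"",,
"D16","Synthetic placeholder device 16","synthetic placeholder; no usable CEA in the appraisal record","",15800,"EUR",FALSE,,,,,,,,,,"",,
"D17","Synthetic placeholder device 17","synthetic placeholder; no usable CEA in the appraisal record","",4900,"EUR",FALSE,,,,,,,,,,"",,
"D18","Synthetic placeholder device 18","synthetic placeholder; no usable CEA in the appraisal record","",21000,"EUR",FALSE,,,,,,,,,,"",,
"D19","Synthetic placeholder device 19","synthetic placeholder; no usable CEA in the appraisal record","",880,"EUR",FALSE,,,,,,,,,,"",,
"D20","Synthetic placeholder device 20","synthetic placeholder; no usable CEA in the appraisal record","",6700,"EUR",FALSE,,,,,,,,,,"",,
"D21","Synthetic placeholder device 21","synthetic placeholder; no usable CEA in the appraisal record","",11400,"EUR",FALSE,,,,,,,,,,"",,
"D22","Synthetic placeholder device 22","synthetic placeholder; no usable CEA in the appraisal record","",2950,"EUR",FALSE,,,,,,,,,,"",,
"D23","Synthetic placeholder device 23","synthetic placeholder; no usable CEA in the appraisal record","",8300,"EUR",FALSE,,,,,,,,,,"",,
"D24","Synthetic placeholder device 24","synthetic placeholder; no usable CEA in the appraisal record","",19900,"EUR",FALSE,,,,,,,,,,"",,
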