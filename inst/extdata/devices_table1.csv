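device_id,name,description,comparator,real_price,real_price_currency,has_cea,gain,outcome_kind,surv1y_a,surv1y_b,cost_b,cost_b_currency,othercosts_a,othercosts_a_currency,time_horizon_months,source,source_kind,reported_vbp_eur
D1,Neovasc Reducer,coronary sinus reducer stent,before-after comparison in included patients,6500,EUR,TRUE,0.138,QALY,,,6988,EUR,8702,EUR,12,Gallone 2020,CEA_registry,6578
D2,Ascyrus Medical Dissection Stent (AMDS),hybrid aortic system for dissections,standard of care,13000,EUR,TRUE,,life_year,0.804,0.756,0,EUR,0,EUR,12,Bozso 2021; Pape 2015,HTA_report,2880
D3,Cardioband,tricuspid valve reconstruction system,standard of care,22000,EUR,TRUE,,life_year,0.36,0.23,0,EUR,0,EUR,12,Taramasso 2019,HTA_report,7800
D4,Pascal Mitral Ace,mitral valve transcatheter repair system,standard of care,22000,EUR,TRUE,1.07,QALY,,,10704,GBP,26471,GBP,lifetime,Shore 2021,HTA_report,45272
D5,Cardia Ultrasept Dia,atrial septal defect closure device,surgical closure,4243,EUR,TRUE,0.03,QALY,,,16000,BRL,6836,BRL,lifetime,Costa 2014,CEA_registry,3579
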