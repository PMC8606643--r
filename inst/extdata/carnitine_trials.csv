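study_id,arm,dose_g_per_day,n,time,time_unit,drug,country,treatment,age_mean,age_sd
El-Sheikh,intervention,2,31,6,months,l-carnitine,Egypt,2 g/day l-carnitine + 4 mg/day glimepiride,50.9,8.6
El-Sheikh,control,0,27,6,months,l-carnitine,Egypt,4 mg/day glimepiride,50.3,8.8
Derosa_orlistat,intervention,2,132,12,months,l-carnitine,Italy,2 g/day l-carnitine + 360 mg/day orlistat,51.0,4.0
Derosa_orlistat,control,0,126,12,months,l-carnitine,Italy,360 mg/day orlistat,53.0,6.0
Derosa_sibutramine,intervention,2,129,12,months,l-carnitine,Italy,2 g/day l-carnitine + 10 mg/day sibutramine,54.0,5.0
Derosa_sibutramine,control,0,125,12,months,l-carnitine,Italy,10 mg/day sibutramine,51.0,4.0
Malaguarnera_simvastatin,intervention,2,40,12,weeks,l-carnitine,Italy,2 g/day l-carnitine + 20 mg/day simvastatin,47.0,13.0
Malaguarnera_simvastatin,control,0,40,12,weeks,l-carnitine,Italy,20 mg/day simvastatin,45.0,12.0
Malaguarnera_placebo,intervention,2,41,3,months,l-carnitine,Italy,2 g/day l-carnitine,49.0,13.0
Malaguarnera_placebo,control,0,40,3,months,l-carnitine,Italy,placebo,48.0,11.0
Galvano,intervention,2,38,4,months,l-carnitine,Italy,2 g/day l-carnitine + 20 mg/day simvastatin,52.1,8.1
Galvano,control,0,37,4,months,l-carnitine,Italy,20 mg/day simvastatin,51.4,7.6
Derosa_placebo,intervention,2,46,6,months,l-carnitine,Italy,2 g/day l-carnitine,52.0,6.0
Derosa_placebo,control,0,48,6,months,l-carnitine,Italy,placebo,50.0,7.0
Liang,intervention,3,23,12,weeks,l-carnitine,China,3 g/day l-carnitine,59.4,1.7
Liang,control,0,23,12,weeks,l-carnitine,China,placebo,57.9,2.6
Parvanova,intervention,2,109,6,months,acetyl-l-carnitine,Italy,2 g/day acetyl-l-carnitine,64.9,7.7
Parvanova,control,0,110,6,months,acetyl-l-carnitine,Italy,placebo,64.6,7.5
Santo,intervention,2,37,12,months,propionyl-l-carnitine,Italy,2 g/day propionyl-l-carnitine,61.75,3.03
Santo,control,0,37,12,months,propionyl-l-carnitine,Italy,placebo,61.26,1.6
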