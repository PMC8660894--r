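"system_code","country","climate_zone","water_regime","ecosystem","establishment","mechanization","field_size","annual_area","cycle_index","season","yield_actual","yield_potential","harvested_area","n_fertilizer","p_fertilizer","k_fertilizer","manure_rate","manure_n_conc","seed_rate","irrigation","precipitation_in_season","labor_hours","straw_management","cultivation_days","water_regime_class","preseason_class","replicate_cycle","pesticide_applications","field_operations","organic_amendments"
"VNIS","VN","tropical","irrigated","lowland","transplanted","intermediate",5.29,412233.8,1,"single",1.493,6.41,412233.8,0,0,0,6876.00922305137,0.005,45.1,946,1046,104.3,"burned",113,"single_drainage","nonflooded_short",FALSE,"herbicide:herbin_a:0.26500000000000001","tillage:6.0551223820075393;harvest:9.1749888667836785;irrigation_pumping:107.2","farmyard_manure:1.7190000000000001"
"THID","TH","non_tropical","irrigated","lowland","transplanted","low",1.6,4312611.4,1,"wet",6.202,9.52,2078861,124.42,57.78,62.32,0,0.005,32.7,1075,295,671.8,"removed",125,"continuously_flooded","nonflooded_short",FALSE,"herbicide:herbin_b:0.23300000000000001;insecticide:insectin_b:0.435;herbicide:herbin_b:0.29699999999999999;herbicide:herbin_b:0.217;herbicide:herbin_a:0.377","tillage:4.2212093996349722;irrigation_pumping:110.2",""
"THID","TH","non_tropical","irrigated","lowland","transplanted","low",1.6,4312611.4,2,"dry",6.17,9.47,2233750.3,90.58,42.07,45.37,0,0.005,43.1,964,530,711.6,"removed",135,"continuously_flooded","nonflooded_short",FALSE,"insecticide:insectin_a:0.35499999999999998;herbicide:herbin_a:0.22800000000000001;herbicide:herbin_b:0.42499999999999999;fungicide:fungin_a:0.38700000000000001;herbicide:herbin_a:0.29299999999999998","tillage:2.4292224212549627;irrigation_pumping:104.3",""
"PHID","PH","tropical","irrigated","lowland","direct_seeded","high",103.86,170673,1,"wet",5.686,8.13,80593.4,148.6,66.18,85.64,0,0.005,149.6,1047,674,35.3,"retained",124,"continuously_flooded","nonflooded_short",FALSE,"herbicide:herbin_a:0.33500000000000002;insecticide:insectin_b:0.35699999999999998;herbicide:herbin_a:0.26600000000000001;insecticide:insectin_a:0.45400000000000001;herbicide:herbin_a:0.25600000000000001;insecticide:insectin_a:0.34699999999999998;herbicide:herbin_b:0.41799999999999998","tillage:12.395963636692613;establishment:5.4778414650354534;fertilizing:2.5762556255795062;harvest:14.348093306645751;irrigation_pumping:95.599999999999994","straw_long:4.8899999999999997"
"PHID","PH","tropical","irrigated","lowland","direct_seeded","high",103.86,170673,2,"dry",5.434,7.77,90079.5,145.83,64.95,84.05,0,0.005,88.9,1337,203,30.3,"retained",117,"continuously_flooded","nonflooded_short",FALSE,"insecticide:insectin_b:0.246;fungicide:fungin_b:0.439;herbicide:herbin_b:0.184;herbicide:herbin_b:0.42099999999999999;insecticide:insectin_a:0.39300000000000002;insecticide:insectin_a:0.373;herbicide:herbin_a:0.219;herbicide:herbin_a:0.43099999999999999;herbicide:herbin_a:0.17299999999999999","tillage:14.176345626357943;establishment:5.6261733015999198;fertilizing:2.7243951763957739;harvest:13.63237021304667;irrigation_pumping:155.5","straw_long:4.6699999999999999"
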