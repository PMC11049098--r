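tier,class,pattern,exempt_category,note
tier1,culinary,salt,,plain cooking salt
tier1,culinary,sea salt,,
tier1,culinary,sugar,,plain sugar in its culinary form
tier1,culinary,brown sugar,,
tier1,culinary,cane sugar,,
tier1,culinary,honey,,
tier1,culinary,molasses,,
tier1,culinary,olive oil,,added culinary oils
tier1,culinary,sunflower oil,,
tier1,culinary,corn oil,,
tier1,culinary,soybean oil,,
tier1,culinary,rapeseed oil,,
tier1,culinary,palm oil,,
tier1,culinary,coconut oil,,
tier1,culinary,vegetable oil,,
tier1,culinary,sesame oil,,
tier1,culinary,oil,,any named oil token
tier1,culinary,butter,,
tier1,culinary,lard,,
tier1,culinary,starch,,culinary starch; modified starch is tier2
tier1,culinary,corn starch,,
tier1,culinary,vinegar,,
tier2,noncaloric_sweeteners,aspartame,,
tier2,noncaloric_sweeteners,sucralose,,
tier2,noncaloric_sweeteners,acesulfame,,
tier2,noncaloric_sweeteners,acesulfame k,,
tier2,noncaloric_sweeteners,saccharin,,
tier2,noncaloric_sweeteners,cyclamate,,
tier2,noncaloric_sweeteners,steviol glycosides,,
tier2,noncaloric_sweeteners,steviol,,
tier2,noncaloric_sweeteners,stevia,,
tier2,noncaloric_sweeteners,sweetener,,
tier2,noncaloric_sweeteners,sweeteners,,
tier2,industrial_caloric_sweeteners,glucose syrup,,
tier2,industrial_caloric_sweeteners,glucose fructose syrup,,
tier2,industrial_caloric_sweeteners,fructose glucose syrup,,
tier2,industrial_caloric_sweeteners,high fructose corn syrup,,
tier2,industrial_caloric_sweeteners,corn syrup,,
tier2,industrial_caloric_sweeteners,invert sugar,,
tier2,industrial_caloric_sweeteners,invert sugar syrup,,
tier2,industrial_caloric_sweeteners,maltodextrin,,
tier2,industrial_caloric_sweeteners,maltodextrins,,
tier2,industrial_caloric_sweeteners,dextrose,,
tier2,industrial_caloric_sweeteners,isoglucose,,
tier2,industrial_caloric_sweeteners,fructose,,
tier2,protein_isolates,protein isolate,,protein isolates or concentrates
tier2,protein_isolates,protein isolates,,
tier2,protein_isolates,protein concentrate,,
tier2,protein_isolates,protein concentrates,,
tier2,protein_isolates,soy protein,,
tier2,protein_isolates,pea protein,,
tier2,protein_isolates,whey protein,,
tier2,protein_isolates,milk protein,,
tier2,protein_isolates,hydrolyzed protein,,
tier2,flavors_enhancers,flavoring,,added natural flavors and flavor enhancers
tier2,flavors_enhancers,flavorings,,
tier2,flavors_enhancers,flavor,,
tier2,flavors_enhancers,flavors,,
tier2,flavors_enhancers,natural flavoring,,
tier2,flavors_enhancers,natural flavor,,
tier2,flavors_enhancers,aroma,,
tier2,flavors_enhancers,aromas,,
tier2,flavors_enhancers,flavor enhancer,,
tier2,flavors_enhancers,monosodium glutamate,,
tier2,flavors_enhancers,yeast extract,,
tier2,emulsifiers,emulsifier,,
tier2,emulsifiers,emulsifiers,,
tier2,emulsifiers,lecithin,,
tier2,emulsifiers,lecithins,,
tier2,emulsifiers,soy lecithin,,
tier2,emulsifiers,sunflower lecithin,,
tier2,emulsifiers,mono and diglycerides,,
tier2,emulsifiers,monoglycerides,,
tier2,emulsifiers,diglycerides,,
tier2,emulsifiers,polysorbate,,
tier2,thickeners_gums,thickener,,bulking agents and other thickeners
tier2,thickeners_gums,thickeners,,
tier2,thickeners_gums,bulking agent,,
tier2,thickeners_gums,sodium carboxymethyl cellulose,,
tier2,thickeners_gums,carboxymethyl cellulose,,
tier2,thickeners_gums,cellulose gel,,
tier2,thickeners_gums,cellulose,,
tier2,thickeners_gums,guar gum,,
tier2,thickeners_gums,xanthan gum,,
tier2,thickeners_gums,locust bean gum,,
tier2,thickeners_gums,gum,,
tier2,thickeners_gums,carrageenan,,
tier2,thickeners_gums,pectin,,
tier2,thickeners_gums,modified starch,,
tier2,antioxidants_preservatives,preservative,,
tier2,antioxidants_preservatives,preservatives,,
tier2,antioxidants_preservatives,antioxidant,,
tier2,antioxidants_preservatives,antioxidants,,
tier2,antioxidants_preservatives,sulfur dioxide,,
tier2,antioxidants_preservatives,sulfites,,
tier2,antioxidants_preservatives,sodium nitrite,,added sodium in industrial forms
tier2,antioxidants_preservatives,sodium nitrate,,
tier2,antioxidants_preservatives,potassium nitrate,,
tier2,antioxidants_preservatives,sodium benzoate,,
tier2,antioxidants_preservatives,potassium sorbate,,
tier2,antioxidants_preservatives,sodium metabisulfite,,
tier2,antioxidants_preservatives,sodium phosphate,,
tier2,antioxidants_preservatives,sodium ascorbate,,
tier2,antioxidants_preservatives,sodium citrate,,
tier2,antioxidants_preservatives,sodium diacetate,,
tier2,antioxidants_preservatives,ascorbyl palmitate,,
tier2,industrial_nutrient_forms,vitamin a palmitate,,nutrient forms rarely used in kitchens
tier2,industrial_nutrient_forms,vitamin d2,,
tier2,industrial_nutrient_forms,vitamin d3,,
tier2,industrial_nutrient_forms,vitamin d,,
tier2,industrial_nutrient_forms,vitamin b12,,
tier2,industrial_nutrient_forms,vitamins,,
tier2,industrial_nutrient_forms,zinc sulfate,,
tier2,industrial_nutrient_forms,ferrous sulfate,,
tier2,industrial_nutrient_forms,calcium carbonate,,
tier2,industrial_nutrient_forms,iron,Grains and Grain Products,milled grains fortified with iron stay NOVA1
tier2,industrial_nutrient_forms,folic acid,Grains and Grain Products,milled grains fortified with folic acid stay NOVA1
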