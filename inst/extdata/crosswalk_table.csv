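model,category,target_model,target_class,intensity_rule,split_group,split_fraction
NLU,Cassava,PREDICTS,annual,yield_shares,,1
NLU,Cassava,PFT,c3_natural_grass,,c3c4_grass,0.9
NLU,Cassava,PFT,c4_natural_grass,,c3c4_grass,0.1
NLU,Fieldpea,PREDICTS,nfixing,yield_shares,,1
NLU,Fieldpea,PFT,c3_summer_crop,,,1
NLU,Groundnut,PREDICTS,nfixing,yield_shares,,1
NLU,Groundnut,PFT,c3_summer_crop,,,1
NLU,Maize,PREDICTS,annual,yield_shares,,1
NLU,Maize,PFT,c4_summer_crop,,,1
NLU,Millet,PREDICTS,annual,yield_shares,,1
NLU,Millet,PFT,c3_summer_crop,,,1
NLU,Rapeseed,PREDICTS,annual,yield_shares,,1
NLU,Rapeseed,PFT,c3_winter_crop,,,1
NLU,Rice,PREDICTS,annual,yield_shares,,1
NLU,Rice,PFT,c3_summer_crop,,,1
NLU,Soybean,PREDICTS,nfixing,yield_shares,,1
NLU,Soybean,PFT,c3_summer_crop,,,1
NLU,Sugarbeet,PREDICTS,annual,yield_shares,,1
NLU,Sugarbeet,PFT,c3_summer_crop,,,1
NLU,Sunflower,PREDICTS,annual,yield_shares,,1
NLU,Sunflower,PFT,c3_summer_crop,,,1
NLU,Wheat,PREDICTS,annual,yield_shares,,1
NLU,Wheat,PFT,c3_winter_crop,,,1
NLU,Other,PREDICTS,annual,yield_shares,other_nlu,0.8
NLU,Other,PREDICTS,perennial,yield_shares,other_nlu,0.2
NLU,Other,PFT,bare_soil,,,1
NLU,Pasture,PREDICTS,pasture,stocking_shares,pasture_range,0.9
NLU,Pasture,PREDICTS,rangeland,none,pasture_range,0.1
NLU,Pasture,PFT,c3_natural_grass,,c3c4_grass,0.9
NLU,Pasture,PFT,c4_natural_grass,,c3c4_grass,0.1
NLU,Forest,PREDICTS,primary,none,primary_secondary,0.5
NLU,Forest,PREDICTS,secondary,none,primary_secondary,0.5
NLU,Forest,PFT,forest_needleleaf_evergreen,,forest_pfts,0.25
NLU,Forest,PFT,forest_broadleaf_evergreen,,forest_pfts,0.25
NLU,Forest,PFT,forest_needleleaf_summergreen,,forest_pfts,0.25
NLU,Forest,PFT,forest_broadleaf_summergreen,,forest_pfts,0.25
NLU,Urban,PREDICTS,urban,none,,1
NLU,Urban,PFT,bare_soil,,,1
AROPAj,Pasture,PREDICTS,pasture,stocking_shares,,1
AROPAj,Pasture,PFT,c3_natural_grass,,c3c4_grass,0.9
AROPAj,Pasture,PFT,c4_natural_grass,,c3c4_grass,0.1
AROPAj,Rangeland,PREDICTS,rangeland,none,,1
AROPAj,Rangeland,PFT,c3_natural_grass,,c3c4_grass,0.9
AROPAj,Rangeland,PFT,c4_natural_grass,,c3c4_grass,0.1
AROPAj,Urban,PREDICTS,urban,none,,1
AROPAj,Urban,PFT,bare_soil,,,1
AROPAj,Other ecosystem,PREDICTS,primary,none,primary_secondary,0.5
AROPAj,Other ecosystem,PREDICTS,secondary,none,primary_secondary,0.5
AROPAj,Other ecosystem,PFT,bare_soil,,,1
AROPAj,Forest,PREDICTS,primary,none,primary_secondary,0.5
AROPAj,Forest,PREDICTS,secondary,none,primary_secondary,0.5
AROPAj,Forest,PFT,forest_needleleaf_evergreen,,forest_pfts,0.25
AROPAj,Forest,PFT,forest_broadleaf_evergreen,,forest_pfts,0.25
AROPAj,Forest,PFT,forest_needleleaf_summergreen,,forest_pfts,0.25
AROPAj,Forest,PFT,forest_broadleaf_summergreen,,forest_pfts,0.25
AROPAj,Durum wheat,PREDICTS,annual,yield_shares,,1
AROPAj,Durum wheat,PFT,c3_winter_crop,,,1
AROPAj,Tender wheat,PREDICTS,annual,yield_shares,,1
AROPAj,Tender wheat,PFT,c3_winter_crop,,,1
AROPAj,Winter barley,PREDICTS,annual,yield_shares,,1
AROPAj,Winter barley,PFT,c3_winter_crop,,,1
AROPAj,Spring barley,PREDICTS,annual,yield_shares,,1
AROPAj,Spring barley,PFT,c3_summer_crop,,,1
AROPAj,Oats,PREDICTS,annual,yield_shares,,1
AROPAj,Oats,PFT,c3_summer_crop,,,1
AROPAj,Other cereals,PREDICTS,annual,yield_shares,,1
AROPAj,Other cereals,PFT,c3_summer_crop,,,1
AROPAj,Rice,PREDICTS,annual,yield_shares,,1
AROPAj,Rice,PFT,c3_summer_crop,,,1
AROPAj,Maize,PREDICTS,annual,yield_shares,,1
AROPAj,Maize,PFT,c4_summer_crop,,,1
AROPAj,Fallow,PREDICTS,annual,minimal,,1
AROPAj,Fallow,PFT,c3_natural_grass,,,1
AROPAj,Beetroot,PREDICTS,annual,yield_shares,,1
AROPAj,Beetroot,PFT,c3_summer_crop,,,1
AROPAj,Rapeseed,PREDICTS,annual,yield_shares,,1
AROPAj,Rapeseed,PFT,c3_winter_crop,,,1
AROPAj,Sunflower,PREDICTS,annual,yield_shares,,1
AROPAj,Sunflower,PFT,c3_summer_crop,,,1
AROPAj,Soybean,PREDICTS,nfixing,yield_shares,,1
AROPAj,Soybean,PFT,c3_natural_grass,,,1
AROPAj,Other legumes,PREDICTS,nfixing,yield_shares,,1
AROPAj,Other legumes,PFT,c3_natural_grass,,,1
AROPAj,Potato,PREDICTS,annual,yield_shares,,1
AROPAj,Potato,PFT,c3_summer_crop,,,1
AROPAj,Perennial,PREDICTS,perennial,yield_shares,,1
AROPAj,Perennial,PFT,c3_natural_grass,,,1
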