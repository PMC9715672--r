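# EU-scale annual-mean indicator levels per scenario family, as reported for
# the two economic scenario archetypes (abandonment: supply-side model;
# extensification: partial-equilibrium model). Units: BII and SR in % of the
# primary-vegetation level, NPP in MtC/yr, soil and biomass carbon in MtC.
family,indicator,baseline,halving_n
abandonment,bii_percent,78.7,80.1
abandonment,sr_percent,83.7,85.7
abandonment,npp_mtc_yr,2102.84,2141.29
abandonment,soil_c_mtc,20706.55,21720.68
abandonment,biomass_c_mtc,11300.24,11605.51
extensification,bii_percent,81,82
extensification,sr_percent,81,80.5
extensification,npp_mtc_yr,2020.10,2017.39
extensification,soil_c_mtc,19487.78,19390.67
extensification,biomass_c_mtc,15541.46,15514.08
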