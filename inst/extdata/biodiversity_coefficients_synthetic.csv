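# Synthetic biodiversity model coefficients (not fitted to any survey data).
# Transforms: sr_coef is on the log scale (Poisson link); the relative SR of a
# class is exp(sr_coef - sr_coef[primary]). abundance_coef is the predicted
# within-study-rescaled sqrt(total abundance); relative abundance is
# (abundance_coef / abundance_coef[primary])^2. similarity_coef is the
# adjusted-logit asymmetric Jaccard similarity to primary-vegetation baseline
# sites; the data-scale value is (plogis(x) - 0.01) / 0.98, clipped to [0, 1],
# and similarity coefficients are coarsened: they may differ across intensity
# only for perennial crops. Reference class: primary vegetation.
class,intensity,sr_coef,abundance_coef,similarity_coef
primary,none,0,1.0,2.77
secondary,none,-0.05,0.95,1.8
annual,minimal,-0.42,0.75,2.0
annual,light,-0.38,0.80,2.0
annual,intense,-0.48,0.65,2.0
perennial,minimal,-0.30,0.85,1.2
perennial,light,-0.34,0.80,0.9
perennial,intense,-0.44,0.70,0.6
nfixing,minimal,-0.40,0.78,1.8
nfixing,light,-0.36,0.80,1.8
nfixing,intense,-0.46,0.70,1.8
pasture,light,-0.05,0.95,0.3
pasture,intense,-0.12,0.85,0.3
rangeland,none,-0.08,0.90,0.5
urban,none,-0.60,0.60,-1.0
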