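study,figure_panel,neuromodulator,manipulation,assay,mean_c,mean_t,dispersion_c,dispersion_t,dispersion_kind,n_c,n_t,digitized_from
example2012,2B,dopamine,activator,PER,0.35,0.62,0.04,0.05,SEM,24,26,synthetic illustration
example2012,3A,dopamine,inhibitor,PER,0.41,0.28,0.05,0.04,SEM,30,28,synthetic illustration
example2014,1C,octopamine,activator,CAFE,0.82,1.61,0.09,0.13,SEM,32,31,synthetic illustration
example2014,1D,octopamine,inhibitor,PER,0.44,0.39,0.05,0.05,SEM,30,30,synthetic illustration
example2016,4B,NPF,inhibitor,CAFE,1.05,0.71,0.30,0.28,SD,20,22,synthetic illustration
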