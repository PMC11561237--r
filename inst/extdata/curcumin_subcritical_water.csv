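temperature_K,dG_solv_kJ_mol,density_g_cm3,density_calc_g_cm3
363.15,-35.848,0.902,0.962
393.15,-35.246,0.896,0.946
413.15,-35.600,0.874,0.935
423.15,-35.400,0.855,0.929
453.15,-35.590,0.781,NA
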