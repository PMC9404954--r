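pairing_id,node_label,node_type,asr_mmc,asr_pmm,divergence,node_age_ma,fossil_genus,fossil_mmc,fossil_pmm,geological_age,fossil_age_mid_ma,include_in_mean,include_in_direction_count
n20_victoriapithecus,20,node,1.07,1.52,16 Ma,16,Victoriapithecus,1.03,1.59,19-12.5 Ma,15.75,TRUE,FALSE
n28_procercocebus,28,node,1.14,1.45,5 Ma,5,Procercocebus,1.13,1.62,2.5 Ma,2.5,TRUE,TRUE
n28_soromandrillus,28,node,1.14,1.45,5 Ma,5,Soromandrillus,1.28,1.78,2-3 Ma,2.5,TRUE,TRUE
n29_procercocebus,29,node,1.10,1.43,2 Ma,2,Procercocebus,1.13,1.62,2.5 Ma,2.5,TRUE,TRUE
n30_soromandrillus,30,node,1.18,1.45,2.5 Ma,2.5,Soromandrillus,1.28,1.78,2-3 Ma,2.5,TRUE,TRUE
n31_parapapio,31,node,1.17,1.66,2 Ma,2,Parapapio,1.18,1.76,2-5 Ma,3.5,TRUE,TRUE
n31_pliopapio,31,node,1.17,1.66,2 Ma,2,Pliopapio,1.20,1.72,4.4 Ma,4.4,TRUE,TRUE
n35_paracolobus,35,node,1.07,1.49,<7.5 Ma,7.5,Paracolobus,1.16,1.50,2-6 Ma,4,TRUE,TRUE
n35_cercopithecoides,35,node,1.07,1.49,<7.5 Ma,7.5,Cercopithecoides,1.18,1.67,2-5 Ma,3.5,TRUE,TRUE
n35_kuseracolobus,35,node,1.07,1.49,<7.5 Ma,7.5,Kuseracolobus,1.17,1.75,4-4.4 Ma,4.2,TRUE,TRUE
n35_libypithecus,35,node,1.07,1.49,<7.5 Ma,7.5,Libypithecus,1.14,1.41,5 Ma,5,TRUE,TRUE
tip_chlorocebus,Chlorocebus aethiops,tip,0.96,1.48,1 Ma,1,cf. Chlorocebus (Ethiopia),0.98,1.56,100-600 ka,0.35,FALSE,TRUE
tip_colobus,Colobus guereza,tip,1.08,1.47,<1.6 Ma,1.6,Colobus sp. (Ethiopia),1.06,1.44,100-600 ka,0.35,FALSE,TRUE
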