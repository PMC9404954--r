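subfamily,tribe,genus,species,n_individuals,source
Cercopithecinae,Cercopithecini,Cercopithecus,sp. (Andalee),30,1
Cercopithecinae,Cercopithecini,Cercopithecus,sp. (Upper Andalee),5,1
Cercopithecinae,Cercopithecini,cf. Chlorocebus,Asbole,13,2
Cercopithecinae,Cercopithecini,cf. Chlorocebus,sp. (Chai Baro),105,3
Cercopithecinae,Cercopithecini,cf. Chlorocebus,sp. (Faro Daba),223,3
Cercopithecinae,Papionini,Papio,hamadryas angusticeps,12,"4, 5"
Cercopithecinae,Papionini,Papio,hamadryas robinsoni,29,"4, 6"
Cercopithecinae,Papionini,Papio,hamadryas ssp. (Asbole),10,2
Cercopithecinae,Papionini,Papio,hamadryas ssp. (Chai Baro),143,3
Cercopithecinae,Papionini,Papio,hamadryas ursinus,1,4
Cercopithecinae,Papionini,Papio,izodi,7,"4, 6, 7"
Cercopithecinae,Papionini,Parapapio,broomi,34,"4, 6, 7"
Cercopithecinae,Papionini,Parapapio,jonesi,12,"4, 7"
Cercopithecinae,Papionini,Parapapio,whitei,16,"4, 6, 7"
Cercopithecinae,Papionini,Pliopapio,alemui,5,8
Cercopithecinae,Papionini,Procercocebus,antiquus,8,"6, 7"
Cercopithecinae,Papionini,Soromandrillus,quadratirostris,11,9
Cercopithecinae,Papionini,Theropithecus,oswaldi cf. darti,124,10
Cercopithecinae,Papionini,Theropithecus,oswaldi darti,4,7
Cercopithecinae,Papionini,Theropithecus,oswaldi leakeyi,12,"2, 11"
Cercopithecinae,Papionini,Theropithecus,oswaldi oswaldi,8,4
Colobinae,Colobini,Cercopithecoides,kimeui,12,"9, 12"
Colobinae,Colobini,Cercopithecoides,meaveae,2,9
Colobinae,Colobini,Cercopithecoides,williamsi,91,9
Colobinae,Colobini,Colobus,cf. guereza (Faro Daba),360,3
Colobinae,Colobini,Colobus,sp. (Andalee),31,1
Colobinae,Colobini,Colobus,sp. (Asbole),47,2
Colobinae,Colobini,Colobus,sp. (Upper Andalee),4,1
Colobinae,Colobini,Kuseracolobus,aramisi,5,8
Colobinae,Colobini,Kuseracolobus,hafu,14,13
Colobinae,Colobini,Libypithecus,markgrafi,3,9
Colobinae,Colobini,Microcolobus,tugenensis,1,9
Colobinae,Colobini,Paracolobus,chemeroni,1,9
Colobinae,Colobini,Paracolobus,enkorikae,8,14
Colobinae,Colobini,Paracolobus,mutiwa,22,9
Colobinae,Colobini,Rhinocolobus,turkanaensis,23,9
Victoriapithecinae,,Victoriapithecus,macinnesi,40,15
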