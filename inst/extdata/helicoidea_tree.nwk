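(((Leptaxinae,(Perforatellini,Hygromiini)Hygromiinae,Trochulininae)Hygromiidae,(Cernuella_virgata,Cochlicella_acuta,(Xerocrassa,Trochoidea_elegans,Trochoidea_pyramidata,Trochoidea_trochoides)Trochoideini)Geomitridae)Hygromiidae_Geomitridae,Helicodonta_obvoluta,((Acusta_ravida,Bradybaena_similaris,Cathaica_fasciola)Camaenidae,(Allogona,Vespericola_columbiana,Cryptomastix_germana,Xolotrema_fosteri,Triodopsis_fraudolenta)Polygyridae)Polygyridae_Camaenidae[&uncertain],Trissexodontidae,Xanthonychidae,(Campylaea_planospira,Theba_pisana,Marmorana_platychela,(Caucasotachea_leucoranea,(Helix_straminea,Helix_gussoneana,Helix_pomatia,Helix_lucorum)Helix)Helicini[&uncertain],(Cornu_apertus,Eobania_vermiculata,Erctella_mazzullii,Otala_lactea)Otalini,Allognathini)Helicidae)Helicoidea;
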