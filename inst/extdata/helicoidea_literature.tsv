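species	family	subfamily	tribe	diploid_number	formula	nor_pairs	source	locality	notes
Helix straminea	Helicidae	Helicinae	Helicini	54	24m+2sm+1st		literature		reference karyotype for the Helix inversion series
Helix pomatia	Helicidae	Helicinae	Helicini	54	18m+8sm+1st		literature		
Caucasotachea leucoranea	Helicidae	Helicinae	Helicini	60			literature		retains the putative ancestral 2n=60 within Helicini
Allognathini	Helicidae	Helicinae	Allognathini	44			literature		tribe-level record; all karyotyped Allognathini have 2n=44
Leptaxinae	Hygromiidae	Leptaxinae		52			literature		subfamily-level record; inherits the Hygromiidae+Geomitridae ancestral 2n=52
Perforatellini	Hygromiidae	Hygromiinae	Perforatellini	48			literature		tribe-level record
Hygromiini	Hygromiidae	Hygromiinae	Hygromiini	42			literature		tribe-level record; lowest diploid number mapped on the tree
Trochulininae	Hygromiidae	Trochulininae		46			literature		subfamily-level record; most species 2n=46
Xerocrassa	Geomitridae	Geomitrinae	Trochoideini	50			literature		genus-level record
Helicodonta obvoluta	Helicodontidae			54			literature		
Trissexodontidae	Trissexodontidae			60			literature		family-level record; conserved ancestral karyotype
Xanthonychidae	Xanthonychidae			60			literature		family-level record; conserved ancestral karyotype
Acusta ravida	Camaenidae	Bradybaeninae		58			literature		7 telocentric pairs
Bradybaena similaris	Camaenidae	Bradybaeninae		56			literature		26 telocentric pairs; 2n=56 via one translocation from 58
Cathaica fasciola	Camaenidae	Bradybaeninae		60			literature		22 telocentric pairs; 2n=60 via one fission from the 2n=58 ancestor
Allogona	Polygyridae			52			literature		genus-level record; two species with 2n=52
Vespericola columbiana	Polygyridae			60			literature		
Cryptomastix germana	Polygyridae			62			literature		
Xolotrema fosteri	Polygyridae			62			literature		NORs on a single pair
Triodopsis fraudolenta	Polygyridae			62			literature		
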