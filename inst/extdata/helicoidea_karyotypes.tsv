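species	family	subfamily	tribe	diploid_number	formula	nor_pairs	source	locality	notes
Monacha sp.	Hygromiidae	Hygromiinae	Monachaini	44			this_study	Portici, Naples, Italy	summary table gives 2n=44 but the karyotype description reports 2n=46 (21m+2sm); conflicting values, unresolved; excluded from the reconstruction tree
Trochoidea elegans	Geomitridae	Geomitrinae	Trochoideini	48	16m+6sm+2t		this_study	Santa Severa, Rome, Italy	karyotype description implies 15m+7sm+2t (7 sm pairs); the printed comparative formula 16m+6sm+2t is used for distances
Trochoidea pyramidata	Geomitridae	Geomitrinae	Trochoideini	48	20m+4sm		this_study	Capri, Naples, Italy	karyotype description implies 21m+3sm (3 sm pairs); the printed comparative formula 20m+4sm is used for distances
Trochoidea trochoides	Geomitridae	Geomitrinae	Trochoideini	48	16m+7sm+1t		this_study	Fusaro, Naples, Italy	karyotype description implies 18m+5sm+1t; printed comparative formula used; printed inversion count from T. pyramidata is 3 while the half-L1 rule gives 4
Cernuella virgata	Geomitridae	Helicellinae	Cernuellini	52	24m+2sm	1	this_study	Seiano, Naples, Italy	NORs on a single pair (ancestral condition in mollusks)
Cochlicella acuta	Geomitridae	Helicellinae	Cochlicellini	52	18m+6sm+1st+1t		this_study	Monte S. Angelo, Naples, Italy	haploid plates n=26; earlier literature reports 2n=46 from Asturias; candidate cryptic lineages, both values retained
Campylaea planospira	Helicidae	Ariantinae		60	29m+1sm		this_study	Amalfi, Salerno, Italy	
Helix gussoneana	Helicidae	Helicinae	Helicini	54	21m+4sm+2st		this_study	Petina, Salerno, Italy	
Helix lucorum	Helicidae	Helicinae	Helicini	54	10m+1sm+16t		this_study	Montellago, Venice, Italy	haploid plates n=27; 16 telocentric pairs, unusual for the superfamily
Cornu apertus	Helicidae	Helicinae	Otalini	54	22m+5sm	4	this_study	Frignano, Caserta, Italy	NORs on four pairs (derived condition)
Eobania vermiculata	Helicidae	Helicinae	Otalini	52	24m+2sm		this_study	Capri, Naples, Italy	NOR-FISH unsuccessful; C-banding+CMA3 positive on 2-3 pairs
Erctella mazzullii	Helicidae	Helicinae	Otalini	54	25m+2sm		this_study	Palermo, Italy	
Otala lactea	Helicidae	Helicinae	Otalini	52	20m+5sm+1t	3	this_study	Morocco	NORs on three pairs (derived condition)
Theba pisana	Helicidae	Helicinae	Thebini	60	30m		this_study	Fusaro, Naples, Italy	all-metacentric complement gradually decreasing in length
Theba pisana	Helicidae	Helicinae	Thebini	60	30m		this_study	Messina, Italy	second population; NOR and heterochromatin patterns match the Fusaro population
Marmorana platychela	Helicidae	Murellinae		60	28m+2sm		this_study	Palermo, Italy	
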