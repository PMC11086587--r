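word,length_letters,n_phonemes,n_syllables,initial_phoneme_id,final_phoneme_id,n_bilabial,n_labiodental,n_dental,n_alveolar,n_palatal,n_velar,n_labiovelar,n_plosive,n_nasal,n_fricative,n_affricate,n_lateral,n_trill,n_tap,n_approximant,n_voiced,n_voiceless,n_front,n_central,n_back,n_open,n_mid,n_close,n_rounded,n_unrounded,ini_bilabial,ini_labiodental,ini_dental,ini_alveolar,ini_palatal,ini_velar,ini_labiovelar,ini_plosive,ini_nasal,ini_fricative,ini_affricate,ini_lateral,ini_trill,ini_tap,ini_approximant,ini_voiced,ini_voiceless,ini_front,ini_central,ini_back,ini_open,ini_mid,ini_close,ini_rounded,ini_unrounded,fin_bilabial,fin_labiodental,fin_dental,fin_alveolar,fin_palatal,fin_velar,fin_labiovelar,fin_plosive,fin_nasal,fin_fricative,fin_affricate,fin_lateral,fin_trill,fin_tap,fin_approximant,fin_voiced,fin_voiceless,fin_front,fin_central,fin_back,fin_open,fin_mid,fin_close,fin_rounded,fin_unrounded,stress_initial,stress_medial,stress_final
general,7,7,3,18,26,0,0,0,3,0,1,0,0,1,1,0,1,0,1,0,3,1,2,1,0,1,2,0,0,3,0,0,0,0,0,1,0,0,0,1,0,0,0,0,0,0,1,0,0,0,0,0,0,0,0,0,0,0,1,0,0,0,0,0,0,0,1,0,0,0,1,0,0,0,0,0,0,0,0,0,0,0,1
panel,5,5,2,6,26,1,0,0,2,0,0,0,1,1,0,0,1,0,0,0,2,1,1,1,0,1,1,0,0,2,1,0,0,0,0,0,0,1,0,0,0,0,0,0,0,0,1,0,0,0,0,0,0,0,0,0,0,0,1,0,0,0,0,0,0,0,1,0,0,0,1,0,0,0,0,0,0,0,0,0,0,0,1
huir,4,3,2,5,29,0,0,0,1,0,0,0,0,0,0,0,0,0,1,0,1,0,1,0,1,0,0,2,1,1,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,1,0,0,1,1,0,0,0,0,1,0,0,0,0,0,0,0,0,0,1,0,1,0,0,0,0,0,0,0,0,0,0,0,1
canal,5,5,2,10,26,0,0,0,2,0,1,0,1,1,0,0,1,0,0,0,2,1,0,2,0,2,0,0,0,2,0,0,0,0,0,1,0,1,0,0,0,0,0,0,0,0,1,0,0,0,0,0,0,0,0,0,0,0,1,0,0,0,0,0,0,0,1,0,0,0,1,0,0,0,0,0,0,0,0,0,0,0,1
cruel,5,5,1,10,26,0,0,0,2,0,1,1,1,0,0,0,1,0,1,1,3,1,1,0,0,0,1,0,0,1,0,0,0,0,0,1,0,1,0,0,0,0,0,0,0,0,1,0,0,0,0,0,0,0,0,0,0,0,1,0,0,0,0,0,0,0,1,0,0,0,1,0,0,0,0,0,0,0,0,0,0,0,1
local,5,5,2,26,26,0,0,0,2,0,1,0,1,0,0,0,2,0,0,0,2,1,0,1,1,1,1,0,1,1,0,0,0,1,0,0,0,0,0,0,0,1,0,0,0,1,0,0,0,0,0,0,0,0,0,0,0,0,1,0,0,0,0,0,0,0,1,0,0,0,1,0,0,0,0,0,0,0,0,0,0,0,1
laurel,6,6,2,26,26,0,0,0,3,0,0,1,0,0,0,0,2,0,1,1,4,0,1,1,0,1,1,0,0,2,0,0,0,1,0,0,0,0,0,0,0,1,0,0,0,1,0,0,0,0,0,0,0,0,0,0,0,0,1,0,0,0,0,0,0,0,1,0,0,0,1,0,0,0,0,0,0,0,0,0,0,0,1
mesa,4,4,2,23,1,1,0,0,1,0,0,0,0,1,1,0,0,0,0,0,1,1,1,1,0,1,1,0,0,2,1,0,0,0,0,0,0,0,1,0,0,0,0,0,0,1,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,1,0,1,0,0,0,1,1,0,0
bala,4,4,2,7,1,1,0,0,1,0,0,0,1,0,0,0,1,0,0,0,2,0,0,2,0,2,0,0,0,2,1,0,0,0,0,0,0,1,0,0,0,0,0,0,0,1,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,1,0,1,0,0,0,1,1,0,0
perro,5,4,2,6,4,1,0,0,1,0,0,0,1,0,0,0,0,1,0,0,1,1,1,0,1,0,2,0,1,1,1,0,0,0,0,0,0,1,0,0,0,0,0,0,0,0,1,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,1,0,1,0,1,0,1,0,0
chico,5,4,2,12,4,0,0,0,0,1,1,0,1,0,0,1,0,0,0,0,0,2,1,0,1,0,1,1,1,1,0,0,0,0,1,0,0,0,0,0,1,0,0,0,0,0,1,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,1,0,1,0,1,0,1,0,0
zapato,6,6,3,14,4,1,0,2,0,0,0,0,2,0,1,0,0,0,0,0,0,3,0,2,1,2,1,0,1,2,0,0,1,0,0,0,0,0,0,1,0,0,0,0,0,0,1,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,1,0,1,0,1,0,0,1,0
yate,4,4,2,19,2,0,0,1,0,1,0,0,1,0,1,0,0,0,0,0,1,1,1,1,0,1,1,0,0,2,0,0,0,0,1,0,0,0,0,1,0,0,0,0,0,1,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,1,0,0,0,1,0,0,1,1,0,0
agua,4,4,2,1,1,0,0,0,0,0,1,1,1,0,0,0,0,0,0,1,2,0,0,2,0,2,0,0,0,2,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,1,0,1,0,0,0,1,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,1,0,1,0,0,0,1,1,0,0
fuego,5,5,2,13,4,0,1,0,0,0,1,1,1,0,1,0,0,0,0,1,2,1,1,0,1,0,2,0,1,1,0,1,0,0,0,0,0,0,0,1,0,0,0,0,0,0,1,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,1,0,1,0,1,0,1,0,0
dedo,4,4,2,9,4,0,0,2,0,0,0,0,2,0,0,0,0,0,0,0,2,0,1,0,1,0,2,0,1,1,0,0,1,0,0,0,0,1,0,0,0,0,0,0,0,1,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,1,0,1,0,1,0,1,0,0
sol,3,3,1,15,26,0,0,0,2,0,0,0,0,0,1,0,1,0,0,0,1,1,0,0,1,0,1,0,1,0,0,0,0,1,0,0,0,0,0,1,0,0,0,0,0,0,1,0,0,0,0,0,0,0,0,0,0,0,1,0,0,0,0,0,0,0,1,0,0,0,1,0,0,0,0,0,0,0,0,0,0,0,1
mar,3,3,1,23,29,1,0,0,1,0,0,0,0,1,0,0,0,0,1,0,2,0,0,1,0,1,0,0,0,1,1,0,0,0,0,0,0,0,1,0,0,0,0,0,0,1,0,0,0,0,0,0,0,0,0,0,0,0,1,0,0,0,0,0,0,0,0,0,1,0,1,0,0,0,0,0,0,0,0,0,0,0,1
flor,4,4,1,13,29,0,1,0,2,0,0,0,0,0,1,0,1,0,1,0,2,1,0,0,1,0,1,0,1,0,0,1,0,0,0,0,0,0,0,1,0,0,0,0,0,0,1,0,0,0,0,0,0,0,0,0,0,0,1,0,0,0,0,0,0,0,0,0,1,0,1,0,0,0,0,0,0,0,0,0,0,0,1
casa,4,4,2,10,1,0,0,0,1,0,1,0,1,0,1,0,0,0,0,0,0,2,0,2,0,2,0,0,0,2,0,0,0,0,0,1,0,1,0,0,0,0,0,0,0,0,1,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,1,0,1,0,0,0,1,1,0,0
vida,4,4,2,7,1,1,0,1,0,0,0,0,2,0,0,0,0,0,0,0,2,0,1,1,0,1,0,1,0,2,1,0,0,0,0,0,0,1,0,0,0,0,0,0,0,1,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,1,0,1,0,0,0,1,1,0,0
tiempo,6,6,2,8,4,2,0,1,0,1,0,0,2,1,0,0,0,0,0,1,2,2,1,0,1,0,2,0,1,1,0,0,1,0,0,0,0,1,0,0,0,0,0,0,0,0,1,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,1,0,1,0,1,0,1,0,0
mujer,5,5,2,23,29,1,0,0,1,0,1,0,0,1,1,0,0,0,1,0,2,1,1,0,1,0,1,1,1,1,1,0,0,0,0,0,0,0,1,0,0,0,0,0,0,1,0,0,0,0,0,0,0,0,0,0,0,0,1,0,0,0,0,0,0,0,0,0,1,0,1,0,0,0,0,0,0,0,0,0,0,0,1
corazon,7,7,3,10,24,0,0,1,2,0,1,0,1,1,1,0,0,0,1,0,2,2,0,1,2,1,2,0,2,1,0,0,0,0,0,1,0,1,0,0,0,0,0,0,0,0,1,0,0,0,0,0,0,0,0,0,0,0,1,0,0,0,0,1,0,0,0,0,0,0,1,0,0,0,0,0,0,0,0,0,0,0,1
arbol,5,5,2,1,26,1,0,0,2,0,0,0,1,0,0,0,1,0,1,0,3,0,0,1,1,1,1,0,1,1,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,1,0,1,0,0,0,1,0,0,0,1,0,0,0,0,0,0,0,1,0,0,0,1,0,0,0,0,0,0,0,0,0,1,0,0
lluvia,6,5,2,27,1,1,0,0,0,2,0,0,1,0,0,0,1,0,0,1,3,0,0,1,1,1,0,1,1,1,0,0,0,0,1,0,0,0,0,0,0,1,0,0,0,1,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,1,0,1,0,0,0,1,1,0,0
libro,5,5,2,26,4,1,0,0,2,0,0,0,1,0,0,0,1,0,1,0,3,0,1,0,1,0,1,1,1,1,0,0,0,1,0,0,0,0,0,0,0,1,0,0,0,1,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,1,0,1,0,1,0,1,0,0
nino,4,4,2,24,4,0,0,0,1,1,0,0,0,2,0,0,0,0,0,0,2,0,1,0,1,0,1,1,1,1,0,0,0,1,0,0,0,0,1,0,0,0,0,0,0,1,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,1,0,1,0,1,0,1,0,0
cantar,6,6,2,10,29,0,0,1,2,0,1,0,2,1,0,0,0,0,1,0,2,2,0,2,0,2,0,0,0,2,0,0,0,0,0,1,0,1,0,0,0,0,0,0,0,0,1,0,0,0,0,0,0,0,0,0,0,0,1,0,0,0,0,0,0,0,0,0,1,0,1,0,0,0,0,0,0,0,0,0,0,0,1
lejos,5,5,2,26,15,0,0,0,2,0,1,0,0,0,2,0,1,0,0,0,1,2,1,0,1,0,2,0,1,1,0,0,0,1,0,0,0,0,0,0,0,1,0,0,0,1,0,0,0,0,0,0,0,0,0,0,0,0,1,0,0,0,0,0,1,0,0,0,0,0,0,1,0,0,0,0,0,0,0,0,1,0,0
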