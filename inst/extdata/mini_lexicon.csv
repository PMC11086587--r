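word,transcription,stress_syllable,pos,valence_mean,valence_sd,arousal_mean,arousal_sd
general,x e . n e . r a l,3,adjective,5.4,1.1,4.2,1.2
panel,p a . n e l,2,noun,5.1,0.9,3.8,1.1
huir,u . i r,2,verb,3.1,1.3,6.4,1.2
canal,k a . n a l,2,noun,5.3,1,4.1,1
cruel,k r w e l,1,adjective,2.2,1.2,6.1,1.3
local,l o . k a l,2,adjective,5.2,0.8,3.9,1
laurel,l a w . r e l,2,noun,6,1.1,3.6,1.1
mesa,m e . s a,1,noun,5.5,0.9,3.2,0.9
bala,b a . l a,1,noun,2.8,1.4,6.8,1.2
perro,p e . rr o,1,noun,6.8,1.2,5.2,1.3
chico,tS i . k o,1,noun,6.1,1,4.6,1.1
zapato,T a . p a . t o,2,noun,5.4,0.8,3.3,0.9
yate,jj a . t e,1,noun,6.5,1.2,4.9,1.3
agua,a . g w a,1,noun,7.2,1,3.9,1.2
fuego,f w e . g o,1,noun,5,1.4,6.9,1.1
dedo,d e . d o,1,noun,5.2,0.7,3.1,0.8
sol,s o l,1,noun,7.5,0.9,5,1.2
mar,m a r,1,noun,7.1,1.1,4.8,1.3
flor,f l o r,1,noun,7.4,0.8,4,1.1
casa,k a . s a,1,noun,7,0.9,3.5,1
vida,b i . d a,1,noun,7.8,1,5.3,1.3
tiempo,t j e m . p o,1,noun,5.6,1.2,4.4,1.2
mujer,m u . x e r,2,noun,6.6,1.1,4.7,1.2
corazon,k o . r a . T o n,3,noun,7.3,1,5.6,1.3
arbol,a r . b o l,1,noun,6.9,0.8,3.4,0.9
lluvia,L u . b j a,1,noun,5.8,1.3,4.3,1.2
libro,l i . b r o,1,noun,6.7,0.9,3.7,1
nino,n i . J o,1,noun,7.2,1.1,5.1,1.3
cantar,k a n . t a r,2,verb,6.8,1,5.5,1.2
lejos,l e . x o s,1,adverb,4.4,1.2,4.1,1.1
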