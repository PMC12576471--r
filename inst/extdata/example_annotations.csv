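name,inchikey,annotation_level,formula,chemical_class,ion_species,mz,rt_min,mass_accuracy_ppm
Uric acid,LEHOTFFKMJEONL-UHFFFAOYSA-N,1,C5H4N4O3,Nitrogenous bases,[M+H]+,169.0356,4.62,-2.4
Isatin,JXDYKVIHCLTXOP-UHFFFAOYSA-N,1,C8H5NO2,Indol,[M+H]+,148.0393,30.73,-2.03
2-Acetylpyrazine,DBZAKQWXICEWNW-UHFFFAOYSA-N,2,C6H6N2O,Alkaloids,[M+H]+,123.0551,4.31,0.98
Schaftoside,MMDUKUSNQNWVET-UHFFFAOYSA-N,2,C26H28O14,Flavonoids,[M+H]+,565.1552,32.19,0.12
Cyclo(proline-leucine),SZJNCZMRZAUNQT-UHFFFAOYNA-N,2,C11H18N2O2,Amino acids and derivatives,[M+H]+,211.1441,28.92,-0.21
ABOA,FZAQRVWPQCXSPC-UHFFFAOYSA-N,2,C9H7NO3,Alkaloids,[M+H]+,178.0499,27.08,-3.58
Caffeic acid,QAIPRVGONGVQAS-DUXPYHPUSA-N,2,C9H8O4,Phenylpropanoids,[M+H]+,181.0495,25.82,-0.05
Syringic acid,JMSVCTWVEWCHDZ-UHFFFAOYSA-N,1,C9H10O5,Phenylpropanoids,[M+H]+,199.0601,26.44,0.41
Catechol,YCIMNLLNPGFGHC-UHFFFAOYSA-N,2,C6H6O2,Phenylpropanoids,[M+H]+,111.0438,28.49,-0.99
Hydroferulic acid,BOLQJTPHPSDZHR-UHFFFAOYSA-N,2,C10H10O3,Phenylpropanoids,[M-H2O+H]+,179.0703,29.25,0.05
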