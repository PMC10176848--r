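community	taxon_id
community 1	o__Saccharimonadales
community 1	g__Sphingomonas
community 1	g__Bradyrhizobium
community 2	g__Neisseria
community 2	g__Alloprevotella
community 2	g__Prevotella
community 2	g__Peptostreptococcus
community 2	g__Haemophilus
community 2	g__Granulicatella
community 3	g__Burkholderia-Caballeronia-Paraburkholderia
community 3	g__Acinetobacter
community 3	g__Rhodococcus
community 4	g__Prevotella_9
community 4	g__Lactobacillus
community 4	g__Megamonas
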