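# Specimen accounting of the packaged drifting-egg barcoding survey
n_selected_eggs: 641
n_hq_eggs: 397
n_hq_larvae: 17
n_species_assigned_eggs: 392
n_genus_assigned_eggs: 2
n_egg_species: 10
n_species_assigned_larvae: 13
n_larva_species: 4
barcode_length: 569
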