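taxon,attachment,divergence_ma,tip_age_ma
Labidosaurus_hamatus,root,323,275
Euparkeria_capensis,Alligator_mississippiensis;Struthio_camelus,237.53,230
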