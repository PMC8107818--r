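animal_id	day	weight_loss_pct	fecal_state	blood_state
m01	1	0	normal	negative
m01	4	3.2	between_normal_semithin	between_neg_occult
m01	8	7.5	semithin	occult
m02	1	0	normal	negative
m02	4	11.0	between_semithin_sparse	occult
m02	8	16.4	sparse	gross
m03	1	0	normal	negative
m03	4	5.0	semithin	between_neg_occult
m03	8	10.0	between_semithin_sparse	between_occult_gross
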