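quantity	value	unit
total_cells_filtered_t0	2.6e5	cells_per_ml
total_cells_filtered_t48	1.56e6	cells_per_ml
total_cells_phosphate_t0	2.2e5	cells_per_ml
total_cells_phosphate_t60	1.79e6	cells_per_ml
total_cells_control_t0	4.7e5	cells_per_ml
total_cells_control_t60	8.5e5	cells_per_ml
nitrogen_total	8.286	umol_per_l
phosphorus_total	0.055	umol_per_l
heterotrophic_bacteria_t0	5.21e8	cells_per_l
aap_bacteria_t0	5.5e7	cells_per_l
aap_cells_t0	5.5e4	cells_per_ml
aap_cells_postfiltration	1.4e4	cells_per_ml
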