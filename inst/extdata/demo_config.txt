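# ervscape demo run: small synthetic study exercising every pipeline stage
seed = 1
n_families = 8
loci_per_family = 30
genome_length = 8000000
input_mean = 20
nb_dispersion = 10
orphan_fraction = 0.3
bin_width = 5000
window_up = 1500
window_down = 8000
bin_size = 50
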