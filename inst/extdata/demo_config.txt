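# Demo configuration: a small synthetic session with a planted
# aIC -> CE_SST lag-1 coupling, 33 Hz aIC-spike/pIC-LFP locking, and
# 80% correct behavior. Keys absent here keep package defaults
# (entrain::default_config()).
session_length = 600
n_trials_per_cs = 6
stage = recall
neurons_aIC = 30
neurons_pIC = 25
neurons_CE_SST = 15
neurons_CE_PKCd = 15
neurons_CEm = 10
coupling_source = aIC
coupling_target = CE_SST
coupling_excess_prob = 0.3
osc_freq = 33
osc_kappa = 4
behavior_correct_prob = 0.8
decode_repeats = 10
te_n_surr = 100
seed = 1
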