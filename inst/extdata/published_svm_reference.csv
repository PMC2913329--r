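# Published test-set operating point of the bare statistical (C-SVC) stage
# of the original model, used as the false-negative reference.
statistic,value
sensitivity,0.841
specificity,0.777
n_mutagen,465
n_nonmutagen,372
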