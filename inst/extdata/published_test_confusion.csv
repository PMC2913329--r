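# Published test-set validation of the original integrated mutagenicity
# cascade (837 compounds): three-output confusion counts by true class.
true_class,mutagenic,nonmutagenic,suspicious
mutagen,403,48,14
nonmutagen,88,268,16
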