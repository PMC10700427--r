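# Size-discrimination experiment with a shortened QUEST+ run.
# Fields override the built-in configuration for experiment 1.
experiment: 1
quest_n_trials: 32
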