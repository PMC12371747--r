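# ggplot2 non-standard-evaluation column names
utils::globalVariables(c("mean_predicted", "observed", "n", "threshold",
                         "net_benefit", "policy"))
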