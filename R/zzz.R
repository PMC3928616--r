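# quiet NSE notes from ggplot2 aesthetics
utils::globalVariables(c("x_um", "v_norm", "config", "y_um", "mV", "what",
                         "curve"))
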