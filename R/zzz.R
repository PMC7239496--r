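utils::globalVariables(c("value_of_param", "value", "coefficient", "metric",
                         "mean_value", "se", "param_value", "row_id", "col_id",
                         "weight"))
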