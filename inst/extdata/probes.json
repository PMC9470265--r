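{
  "pro12a": {"lambda_lo": 423, "lambda_ld": 494, "excitation_nm": 405,
             "channels": {"n": 20, "from": 423, "to": 601}},
  "nr12s":  {"lambda_lo": 557, "lambda_ld": 664, "excitation_nm": 488,
             "channels": {"n": 22, "from": 503, "to": 700}},
  "nr12a":  {"lambda_lo": 583, "lambda_ld": 673, "excitation_nm": 488,
             "channels": {"n": 22, "from": 503, "to": 700}}
}
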