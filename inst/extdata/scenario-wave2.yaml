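p_accept: 0.807
p_dropout_after_day0: 0.009
p_engage: 0.914
p_snooze: 0.39
'n': 140
seed: 20200801
start_date: '2020-09-01'
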