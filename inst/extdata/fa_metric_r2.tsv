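subject	fiber_count	fiber_length	visc
C13	0.131	0.200	0.195
C17	0.174	0.217	0.192
C18	0.176	0.220	0.204
C19	0.134	0.220	0.204
C20	0.075	0.166	0.192
C21	0.175	0.211	0.201
C23	0.120	0.171	0.154
C26	0.139	0.225	0.179
S01	0.168	0.248	0.206
S02	0.208	0.256	0.249
S04	0.125	0.199	0.174
S10	0.143	0.207	0.186
S11	0.166	0.203	0.176
S13	0.150	0.222	0.192
S14	0.154	0.206	0.193
S15	0.142	0.175	0.170
S17	0.026	0.072	0.084
S19	0.118	0.153	0.158
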