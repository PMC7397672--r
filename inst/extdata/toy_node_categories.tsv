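R0	receptor
s1	signaling
s2	signaling
s3	signaling
s4	signaling
s5	signaling
s6	signaling
s7	signaling
s8	signaling
s9	signaling
s10	signaling
s11	signaling
s12	signaling
s13	signaling
s14	signaling
s15	signaling
s16	signaling
s17	signaling
s18	signaling
s19	signaling
s20	signaling
tf1	transcription_factor
tf2	transcription_factor
tf3	transcription_factor
tf4	transcription_factor
tf5	transcription_factor
tf6	transcription_factor
tf7	transcription_factor
tf8	transcription_factor
tf9	transcription_factor
tf10	transcription_factor
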