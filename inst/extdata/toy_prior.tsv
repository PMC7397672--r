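R0	s17
R0	s5
R0	s1
R0	s10
s1	s18
s1	s16
s2	s5
s2	s6
s2	s15
s3	s19
s3	s16
s4	s10
s4	s5
s4	s6
s5	s14
s5	s6
s5	s2
s6	s1
s6	s11
s6	s12
s7	s9
s7	s4
s7	s19
s8	s19
s8	s14
s9	s4
s10	s19
s10	s3
s11	s18
s11	s19
s11	s6
s12	s2
s12	s3
s13	s2
s13	s6
s14	s10
s14	s8
s15	s1
s16	s7
s17	s10
s18	s12
s19	s11
s20	s16
s20	s5
s20	s14
s2	tf1
s17	tf2
s18	tf2
s14	tf3
s8	tf4
s4	tf4
s19	tf4
s10	tf5
s18	tf5
s13	tf5
s19	tf6
s17	tf7
s12	tf7
s11	tf8
s16	tf9
s6	tf10
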