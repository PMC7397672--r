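tf1	g13
tf1	g14
tf1	g5
tf1	g9
tf2	g14
tf2	g15
tf2	g16
tf2	g17
tf2	g25
tf2	g26
tf2	g29
tf2	g32
tf2	g33
tf2	g6
tf3	g16
tf3	g22
tf3	g30
tf3	g31
tf3	g32
tf3	g34
tf3	g37
tf3	g38
tf3	g40
tf3	g6
tf4	g1
tf4	g12
tf4	g15
tf4	g2
tf4	g20
tf4	g23
tf4	g24
tf4	g26
tf4	g34
tf5	g14
tf5	g2
tf5	g25
tf5	g28
tf5	g34
tf6	g10
tf6	g14
tf6	g26
tf6	g27
tf6	g28
tf6	g32
tf6	g34
tf6	g37
tf6	g38
tf6	g5
tf7	g26
tf7	g31
tf7	g35
tf7	g37
tf8	g11
tf8	g17
tf8	g20
tf8	g27
tf8	g30
tf8	g32
tf8	g36
tf8	g39
tf9	g1
tf9	g13
tf9	g17
tf9	g31
tf10	g2
tf10	g28
tf10	g31
tf10	g33
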