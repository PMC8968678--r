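# Unified nearest-neighbor thermodynamic parameters for DNA duplexes
# (SantaLucia unified set, 1 M NaCl reference state).
# pair: 5'->3' dinucleotide on the top strand; the ten unique stacks are
# listed, the remaining six follow by reverse complementation.
# INIT_AT / INIT_GC: duplex initiation terms per terminal A:T / G:C pair.
# SYM: entropic symmetry correction applied to self-complementary duplexes.
# dH in kcal/mol, dS in cal/(mol*K).
pair	dH_kcal_mol	dS_cal_molK
AA	-7.9	-22.2
AT	-7.2	-20.4
TA	-7.2	-21.3
CA	-8.5	-22.7
GT	-8.4	-22.4
CT	-7.8	-21.0
GA	-8.2	-22.2
CG	-10.6	-27.2
GC	-9.8	-24.4
GG	-8.0	-19.9
INIT_AT	2.3	4.1
INIT_GC	0.1	-2.8
SYM	0.0	-1.4
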