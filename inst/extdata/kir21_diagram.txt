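# Kir2.1 eleven-state permeation diagram (wild-type topology)
#
# States: four selectivity-filter sites S1..S4 listed extracellular -> intracellular,
# each holding an ion (i) or a water (w), plus a lumped wide-pore K+ site
# (pore = 1 occupied, 0 empty). Adjacent filter sites never both hold an ion,
# and the ion-empty filter is excluded.
#
# Edges: one row per undirected transition. "fwd" is the direction written
# from -> to. Labels k1..k10 are the free rate constants (value at 0 mV);
# "dep" marks a direction whose rate is computed from thermodynamic cyclic
# reversibility (detailed balance) at run time -- one per independent loop.
# conc: "in"/"out" marks bimolecular directions scaled by intracellular /
# extracellular [K+] (k0 then has units s-1 M-1); "none" is unimolecular.
# z: electrical distance of the directed rate (NA for dependent directions,
# where it is implied by the loop constraint).
# ion_out / water_out: ions / waters crossing the extracellular reference
# plane when the fwd transition fires (+ = efflux). ion_in: ions entering
# the wide-pore site from the intracellular bulk (+ = binding).
# Reverse directions negate all three transfer numbers.
[states]
index	sf	pore
1	i-w-i-w	0
2	i-w-i-w	1
3	w-i-w-i	0
4	w-w-i-w	1
5	w-i-w-w	0
6	w-i-w-w	1
7	w-w-i-w	0
8	w-w-w-i	0
9	i-w-w-i	0
10	i-w-w-w	0
11	i-w-w-w	1
[edges]
from	to	fwd	bwd	fwd_z	bwd_z	fwd_conc	bwd_conc	ion_out	water_out	ion_in
1	2	k1	k2	0	0	in	none	0	0	1
5	6	k1	k2	0	0	in	none	0	0	1
10	11	k1	k2	0	0	in	none	0	0	1
7	4	k1	dep	0	NA	in	none	0	0	1
1	5	k3	k4	0.2	-0.2	none	out	1	0	0
9	7	k3	k4	0.2	-0.2	none	out	1	0	0
1	7	k6	dep	0.2	NA	none	out	1	-1	0
2	4	k6	dep	0.2	NA	none	out	1	-1	0
2	3	k7	dep	0.2	NA	none	out	1	0	0
6	9	k7	dep	0.2	NA	none	none	0	1	0
11	8	k5	dep	0.3	NA	none	out	1	0	0
11	9	k7	k8	0.2	-0.2	none	none	0	0	0
3	1	k9	k10	0.1	-0.1	none	none	0	1	0
5	10	k9	k10	0.1	-0.1	none	none	0	1	0
8	7	k9	k10	0.1	-0.1	none	none	0	1	0
4	6	k9	k10	0.1	-0.1	none	none	0	1	0
6	11	k9	dep	0.1	NA	none	none	0	1	0
[checksum]
states	11
transitions	17
directed_rates	34
simple_cycles	59
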