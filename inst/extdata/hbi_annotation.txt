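# Default annotation for the Scapharca inaequivalvis dimeric hemoglobin (HbI).
#
# The helix residue ranges below are a reconstructed globin-fold default
# (146-residue chain), pinned by the published residue/helix anchors:
# His69 on the E helix, Phe97 on the F helix, Ile25 on the B helix,
# Ile114 on the G helix, Val121/Ser124/Lys125 on the H helix. They are a
# replaceable data default, not an algorithmic constant: supply your own
# file to override. The FG corner is declared as a pseudo-region so portal
# classification can report "corner:FG".
#
# Cavity lining residues: the B (distal docking), Xe1, Xe2 and Xe4 pockets
# are anchored by the published associations Ile25<->Xe4 and Ile114<->Xe2;
# the remaining lining residues are defaults derived from the xenon-binding
# literature on this protein and are likewise replaceable.

helix A A 4 18
helix A B 21 36
helix A C 37 44
helix A D 52 58
helix A E 60 79
helix A F 86 98
corner A FG 99 100
helix A G 101 118
helix A H 121 142

helix B A 4 18
helix B B 21 36
helix B C 37 44
helix B D 52 58
helix B E 60 79
helix B F 86 98
corner B FG 99 100
helix B G 101 118
helix B H 121 142

cavity B A 4.5
cavity_residue B A 36
cavity_residue B A 37
cavity_residue B A 69
cavity_residue B A 97

cavity Xe4 A 4.5
cavity_residue Xe4 A 21
cavity_residue Xe4 A 25
cavity_residue Xe4 A 32
cavity_residue Xe4 A 35

cavity Xe2 A 4.5
cavity_residue Xe2 A 90
cavity_residue Xe2 A 94
cavity_residue Xe2 A 110
cavity_residue Xe2 A 114

cavity Xe1 A 4.5
cavity_residue Xe1 A 7
cavity_residue Xe1 A 10
cavity_residue Xe1 A 104
cavity_residue Xe1 A 107

cavity B B 4.5
cavity_residue B B 36
cavity_residue B B 37
cavity_residue B B 69
cavity_residue B B 97

cavity Xe4 B 4.5
cavity_residue Xe4 B 21
cavity_residue Xe4 B 25
cavity_residue Xe4 B 32
cavity_residue Xe4 B 35

cavity Xe2 B 4.5
cavity_residue Xe2 B 90
cavity_residue Xe2 B 94
cavity_residue Xe2 B 110
cavity_residue Xe2 B 114

cavity Xe1 B 4.5
cavity_residue Xe1 B 7
cavity_residue Xe1 B 10
cavity_residue Xe1 B 104
cavity_residue Xe1 B 107
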