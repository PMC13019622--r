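system basis geometry n_orbitals e_rhf_hartree e_fci_hartree
h2 STO-3G "R = 1.4 bohr" 2 -1.1167143252 -1.1372759438
he STO-3G "atom" 1 -2.8077839566 -2.8077839566
lih STO-3G "R = 3.015 bohr" 6 -7.8620092860 -7.8823949714
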