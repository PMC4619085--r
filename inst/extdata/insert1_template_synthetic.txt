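# Default Insert-1 oligo template (synthetic).
# Constant segments of the single 165-nt starting oligo:
#   gibson5 + t_u6(20) + scaffold_frag + bsmbi_cassette + t_h1(20)
#   + h1_frag + gibson3
# The five constant segments total 125 nt, so any two 20-nt targeting
# sequences yield a 165-nt oligo. The cassette carries the two outward-
# cutting BsmBI sites (one per strand) removed in cloning step 2.
# These segment sequences are synthetic stand-ins for the published
# template, chosen to satisfy the structural constraints of the format.
gibson5=ATCTTGTGGAAAGGACGAAACACCG
scaffold_frag=GTTTTAGAGCTAGAAATAGC
bsmbi_cassette=CACCTGCAGAGACGACCGACTAGTCGTCTCCAGCA
h1_frag=CTGGGAAATCACCATAAACGTGAAA
gibson3=GGTTCGTGGTCCCGAGTCAC
t2_orientation=sense
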