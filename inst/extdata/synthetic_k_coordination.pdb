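REMARK   1 SYNTHETIC fixture: K+ ion with two first-shell water oxygens
REMARK   1 at 2.80 A and four bulk waters beyond 5 A (constructed, not
REMARK   1 an experimental structure)
HETATM    1 K      K A 500       0.000   0.000   0.000  1.00  0.00           K
HETATM    2 O    HOH A 601       2.800   0.000   0.000  1.00  0.00           O
HETATM    3 O    HOH A 602      -2.800   0.000   0.000  1.00  0.00           O
HETATM    4 O    HOH A 603       0.000   6.500   0.000  1.00  0.00           O
HETATM    5 O    HOH A 604       0.000  -7.200   1.000  1.00  0.00           O
HETATM    6 O    HOH A 605       5.500   5.500   0.000  1.00  0.00           O
HETATM    7 O    HOH A 606       0.000   0.000   9.100  1.00  0.00           O
END
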