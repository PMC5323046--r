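# Curated autophagy / mTORC1 / lysosome panel (gene symbols, one per line)
ULK1
RPS6KB1
WIPI2
ATG3
ATG7
ATG12
ATG13
ATG14
ATF4
LAMP1
LAMP2
MAP1LC3B
GABARAP
STX17
RB1CC1
ATG101
PIK3C3
BECN1
TFEB
SQSTM1
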