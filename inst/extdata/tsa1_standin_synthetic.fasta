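>tsa1_standin_synthetic | synthetic stand-in for the 196-residue yeast peroxiredoxin chain; composition matched to published aggregate properties (not the database sequence)
LGFKHISDGFGAKINGSNQHLREETYNDGIGVYFNSHMVYDASYFLCVTANKRRYVGVKP
GLETLEVLTGIKANQAIPQNEISLLASLAGHTSARKPFYEPINAFALEVPMFETWVARPV
KNNSPPWLNKTSNNSPGRTMAAYRLIVSRGEVLGGIGHQYTNLEALRPTCSTGSVAIVQK
PKQMKPQYDLELAGEI
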