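>SYNEPI_001 synthetic stand-in reference epitope (randomly generated, not from any curated immune database)
LMYDPTQRV
>SYNEPI_002 synthetic stand-in reference epitope
KVFERATSL
>SYNEPI_003 synthetic stand-in reference epitope
GQWNHTIDLK
>SYNEPI_004 synthetic stand-in reference epitope
YSTRAELMNV
>SYNEPI_005 synthetic stand-in reference epitope
RPHGDWKFAY
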