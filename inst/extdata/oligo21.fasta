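>oligo21_top 21 bp duplex, top strand 5'->3'
CTCAATTGGTCGTAGACAGCT
>oligo21_bottom 21 bp duplex, bottom strand 5'->3'
AGCTGTCTACGACCAATTGAG
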