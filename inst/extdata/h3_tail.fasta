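>H3_tail_1-44 histone H3 N-terminal tail construct
ARTKQTARKSTGGKAPRKQLATKAARKSAPATGGVKKPHRYRPG
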