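>ref
ACDPEFGWHIKL
>seq2
ACDPEFGWHIKL
>seq3
ACEPDFGWHIKL
>seq4
ACDHEFGYHIKL
>seq5
ACDHEFGYHIKL
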