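>J101
CGTAACAAGGTTTCCGTAGGTGAA
>J102
CGTAACAAGGTTTCCGTAGGTGAA
>J201
CGTAACAAGGT--CCGTAGGTGAA
>J202
CGTAACAAGGT--CCGTAGGTGAA
>J301
CGAAACAAGGTTTCAGTGGGTGAA
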