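>J101 voucher Litsea elongata
ATGTCACCACAAACAGAGACTAAAGCAAGT
>J102 voucher Litsea elongata
ATGTCACCACAAACAGAGACTAAAGCAAGT
>J201 voucher Litsea salicifolia
ATGTCACCACAAACAGAGACTAAGGCAAGT
>J202 voucher Litsea salicifolia
ATGTCACCACAAACAGAGACTAAGGCAAGT
>J301 voucher Machilus grijsii
ATGTCTCCACAAACGGAGACTAGAGCGAGT
>J302 voucher Machilus grijsii
ATGTCTCCACAAACGGAGACTAGAGCGAGT
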