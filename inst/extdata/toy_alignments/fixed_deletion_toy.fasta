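>toy_fixed_del|sister1|1
ACGTACGT-TGCATGCA
>toy_fixed_del|sister1|2
ACGTACGT-TGCATGCA
>toy_fixed_del|sister2|1
ACGTACGTATGCATGCA
>toy_fixed_del|sister2|2
ACGTACGTATGCATGCA
>toy_fixed_del|outgroup|1
ACGTACGTATGCATGCA
>toy_fixed_del|outgroup|2
ACGTACGTATGCATGCA
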