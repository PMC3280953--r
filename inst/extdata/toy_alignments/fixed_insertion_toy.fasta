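>toy_fixed_ins|sister1|1
ACGTACGTATGCATGCA
>toy_fixed_ins|sister1|2
ACGTACGTATGCATGCA
>toy_fixed_ins|sister2|1
ACGTACGT-TGCATGCA
>toy_fixed_ins|sister2|2
ACGTACGT-TGCATGCA
>toy_fixed_ins|outgroup|1
ACGTACGT-TGCATGCA
>toy_fixed_ins|outgroup|2
ACGTACGT-TGCATGCA
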