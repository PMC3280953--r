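>toy_conv_ins|sister1|1
ACGTACGTATGCATGCA
>toy_conv_ins|sister1|2
ACGTACGTATGCATGCA
>toy_conv_ins|sister2|1
ACGTACGTATGCATGCA
>toy_conv_ins|sister2|2
ACGTACGT-TGCATGCA
>toy_conv_ins|outgroup|1
ACGTACGTATGCATGCA
>toy_conv_ins|outgroup|2
ACGTACGT-TGCATGCA
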