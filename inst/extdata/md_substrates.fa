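>AGCT_strong
TACGGTAGTAGCTACTTTGACT
>AGCT_weak
CCTACATGCAGCTCAGCAGCCT
>AACT_strong
TACGGTAGTAACTACTTTGACT
>TGCA_strong
TACGGTAGTTGCAACTTTGACT
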