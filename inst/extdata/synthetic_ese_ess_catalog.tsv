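sequence	role	annotation
GAAGAA	ESE	synthetic catalog; SR-protein-like purine-rich enhancer
GAAGAA	ESE	synthetic catalog; duplicate listing, second source entry
GAAGGA	ESE	synthetic catalog; purine-rich enhancer
AAGAAG	ESE	synthetic catalog; purine-rich enhancer
TGGAAG	ESE	synthetic catalog; enhancer hexamer
GACGTC	ESE	synthetic catalog; enhancer hexamer
CACACG	ESE	synthetic catalog; enhancer hexamer
GGAAGR	ESE	synthetic catalog; degenerate purine-rich enhancer
TCCTCC	ESE	synthetic catalog; pyrimidine enhancer-like hexamer
AGGAGG	ESE	synthetic catalog; enhancer hexamer
CTCTTC	ESE	synthetic catalog; enhancer hexamer
GAAGAT	ESE	synthetic catalog; enhancer hexamer
TAGGGT	ESS	synthetic catalog; hnRNP-A1-like silencer
TAGACA	ESS	synthetic catalog; hnRNP-A1-like silencer
TCTTCT	ESS	synthetic catalog; PTB-like pyrimidine silencer
CTCTCT	ESS	synthetic catalog; pyrimidine silencer
TTAGGG	ESS	synthetic catalog; silencer hexamer
GGGTGG	ESS	synthetic catalog; G-rich silencer
GGTGGG	ESS	synthetic catalog; G-rich silencer
TTCTCC	ESS	synthetic catalog; silencer hexamer
ATAGAC	ESS	synthetic catalog; silencer hexamer
TAGG	ESE	synthetic catalog; short dual-role motif, enhancer listing
TAGG	ESS	synthetic catalog; short dual-role motif, silencer listing
GGGG	ESE	synthetic catalog; G-run, enhancer listing
GGGG	ESS	synthetic catalog; G-run, silencer listing
YCAY	ESS	synthetic catalog; degenerate silencer tetramer
ACGAGC	ESE	synthetic catalog; enhancer hexamer
CGACGA	ESE	synthetic catalog; enhancer hexamer
TGTTGT	ESS	synthetic catalog; silencer hexamer
ATTTA	ESS	synthetic catalog; AU-rich silencer pentamer
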