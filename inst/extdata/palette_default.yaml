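DOMAIN_MIN:
- 0
- 0
- 0
BG_HALF_PILOW:
- 32
- 0
- 64
BG_PILOW:
- 64
- 0
- 128
BG_MEAN:
- 0
- 64
- 255
GM_MEAN:
- 0
- 160
- 96
GM_PIUP:
- 96
- 192
- 0
CCF_PILOW:
- 255
- 0
- 0
CCF_PIUP:
- 255
- 128
- 0
CCROI_MEAN:
- 255
- 255
- 0
DOMAIN_MAX:
- 255
- 255
- 255
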