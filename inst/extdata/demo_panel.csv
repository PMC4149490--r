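plate,well,antigen,fluorochrome,clone
P1,A1,CD45,PE,HI30
P1,A2,CD3,FITC,UCHT1
P1,A3,CD19,APC,HIB19
P1,A4,CD14,PE,M5E2
P1,A5,CD11b,FITC,ICRF44
P1,A6,CD56,APC,HCD56
P1,A7,CD4,PE,RPA-T4
P1,A8,CD8,FITC,RPA-T8
P1,A9,EpCAM,APC,9C4
P1,A10,CD24,PE,ML5
P1,A11,CD44,FITC,BJ18
P1,A12,CD49f,APC,GoH3
P1,B1,CD104,PE,58XB4
P1,B2,CAIX,FITC,303123
P1,B3,CD10,APC,HI10a
P1,B4,CD146,PE,P1H12
P1,B5,CD90,FITC,5E10
P1,B6,CD73,APC,AD2
P1,B7,CD105,PE,43A3
P1,B8,CD140b,FITC,18A2
P1,B9,CD26,APC,BA5b
P1,B10,CD54,PE,HA58
P1,B11,CD29,FITC,TS2/16
P1,B12,HLA-ABC,APC,W6/32
P1,C1,CONTROL,PE,
P1,C2,CONTROL,FITC,
P1,C3,CONTROL,APC,
P1,C4,CONTROL,NONE,
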