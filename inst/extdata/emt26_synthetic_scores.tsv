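Cdh1 1
miR200a 0
miR200b 1
miR200c 0
miR141 0
miR34a 1
miR101 0
miR205 0
miR30c 0
Ovol2 0
Grhl2 0
Zeb1 -1
Zeb2 0
Snai1 -1
Snai2 0
Twist1 0
Twist2 0
Foxc2 0
Vim -1
Tgfb 0
Gsc 0
Klf8 0
Tcf3 0
Fn1 0
Sparc 0
Mmp9 0
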