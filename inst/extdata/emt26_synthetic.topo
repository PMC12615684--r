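Source Target Type
Zeb1 Zeb1 1
Zeb1 Cdh1 2
Zeb1 miR200a 2
Zeb1 miR200b 2
Zeb1 miR200c 2
Zeb1 miR141 2
Zeb1 miR34a 2
Zeb1 miR101 2
Zeb1 Vim 1
Zeb1 Fn1 1
Zeb1 Foxc2 1
Snai1 Snai1 2
Snai1 Cdh1 2
Snai1 miR200b 2
Snai1 miR34a 2
Snai1 miR141 2
Snai1 Zeb1 1
Snai1 Zeb2 1
Snai1 Twist1 1
Snai1 Vim 1
Snai1 Klf8 1
miR200a Zeb1 2
miR200b Zeb1 2
miR200c Zeb1 2
miR200a Zeb2 2
miR200b Zeb2 2
miR200c Zeb2 2
miR34a Snai1 2
miR34a Snai2 2
miR141 Zeb2 2
miR101 Zeb1 2
miR205 Zeb2 2
miR30c Snai1 2
Grhl2 Cdh1 1
Grhl2 miR200b 1
Ovol2 Cdh1 1
Ovol2 miR34a 1
Grhl2 Zeb1 2
Ovol2 Zeb1 2
Cdh1 miR200a 1
Cdh1 miR34a 1
Tgfb Snai1 1
Tgfb Zeb2 1
Tgfb Twist1 1
Tgfb miR200c 2
Snai2 Cdh1 2
Snai2 miR200a 2
Snai2 Zeb1 1
Zeb2 Cdh1 2
Zeb2 miR200c 2
Zeb2 Vim 1
Twist1 Snai2 1
Twist1 Zeb2 1
Twist1 Fn1 1
Twist1 Cdh1 2
Twist2 Snai2 1
Twist2 Vim 1
Twist2 Cdh1 2
Foxc2 Vim 1
Foxc2 Mmp9 1
Klf8 Cdh1 2
Tcf3 Cdh1 2
Gsc Snai1 1
Cdh1 miR200b 1
miR200a Cdh1 1
miR200b Cdh1 1
miR200c Cdh1 1
miR141 Cdh1 1
miR34a Cdh1 1
miR101 Cdh1 1
miR205 Cdh1 1
miR30c Cdh1 1
Ovol2 miR200a 1
Grhl2 miR200a 1
Zeb2 miR200a 2
Snai2 miR200b 2
Twist1 miR200a 2
Twist2 miR200a 2
Foxc2 Cdh1 2
Vim Cdh1 2
Tgfb Cdh1 2
Gsc Cdh1 2
Klf8 miR200a 2
Tcf3 miR200a 2
Fn1 Cdh1 2
Sparc Cdh1 2
Mmp9 Cdh1 2
Cdh1 miR200c 1
miR200a miR200b 1
miR200b miR200a 1
miR200c miR200a 1
miR141 miR200a 1
miR34a miR200a 1
miR101 miR200a 1
miR205 miR200a 1
miR30c miR200a 1
Ovol2 miR200b 1
Grhl2 miR200c 1
Zeb2 miR200b 2
Snai2 miR200c 2
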