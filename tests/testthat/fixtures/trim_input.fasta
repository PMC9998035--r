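>r01
ACD-E-G-
>r02
A-D-E-G-
>r03
A---E-G-
>r04
A---E-G-
>r05
A---E-G-
>r06
A---E-G-
>r07
A---E-G-
>r08
A---E-G-
>r09
A---E-G-
>r10
A---E-GH
>r11
A---E-G-
>r12
A---E-G-
>r13
A---E-G-
>r14
A---E-G-
>r15
A---E-G-
>r16
A-----G-
>r17
A-----G-
>r18
A-----G-
>r19
A-----G-
>r20
A-----GH
>r21
A-----G-
>r22
A-----G-
>r23
A-----G-
>r24
A-----G-
>r25
A-----G-
>r26
A-----G-
>r27
A-----G-
>r28
A-----G-
>r29
A-----G-
>r30
A----FG-
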