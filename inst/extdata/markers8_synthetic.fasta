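>marker01 synthetic Poly_export marker
TYGTVDTEWDAAPMFGSGPPFYTCADHPTSGWQYYCTYSDMEIVFHHYMSPNKNVECGRCISMRLTMMNRALIHGIDRHTICVLYASCSKD
>marker02 synthetic Poly_export marker
TYGFVDTEWDAAPMFGSGPPFYKCADHPTSGWQPHCTYSDMEIVRHHYMSFRKNVECPRCISMRLTMMVRALIHGIDRNTICVLYASRGKD
>marker03 synthetic Poly_export marker
TYGTVDAMWDAAPMFGSGPYFSKDADSPTSGWQPYCTYSDYEIVRHHYMSPRKNVECIRCISMRLTMMNIALYHGIDRHTICVDYASCSKD
>marker04 synthetic Poly_export marker
LYGTVDTEWDAAPLFGSGPPFYKCADHPTSKWQPYCTYSDMAIVRKHYISPRKNVECGRVEAMALTMMNRATIHGVDRHTICVLYASIWKD
>marker05 synthetic Poly_export marker
TYRTVDNEWDNAPMFGSGPPVRKCADHVTSNWQPACTYSHMHIVRHHLMSPRKAVECGRYISMRLTMMVRHLTHGIDIHTIKVLYASCGKD
>marker06 synthetic Poly_export marker
TQGTVDTESTLLPMMGLGPPFGQCAEPPESGWQKWCTYSAMEQVRQHYMSPRKNVECGRCISMRLEMMNRAPIHGIHNHTRCVLYASFSKP
>marker07 synthetic Poly_export marker
FYATRFTEVAAWCMFGGGPSQYKCMDNCTSGWQPYCCYSDTGIVRHIQMSPRKDWTCGRCISTRRTMQNRALIHGIDRHNICVQYASCQKD
>marker08 synthetic Poly_export marker
QYGVYDTEWDAAIMFGSAPPSYKPAIWPQHTLQPYLTLRTMEIKRHHYMDWVKFVECFRCISDMLTMSNRALIHGIDQATIGVVYASCSKH
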