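#                                                                            --- full sequence --- -------------- this domain -------------   hmm coord   ali coord   env coord
# target name        accession   tlen query name           accession   qlen   E-value  score  bias   #  of  c-Evalue  i-Evalue  score  bias  from    to  from    to  from    to  acc description of target
#------------------- ---------- ----- -------------------- ---------- ----- --------- ------ ----- --- --- --------- --------- ------ ----- ----- ----- ----- ----- ----- ----- ---- ---------------------
Poly_export          PF02563.20    91 WzaEc_like           -            115   1.6e-38   78.3   0.0   1   1   1.6e-38  1.58e-38   78.3   0.0     1    91    25   115    25   115 0.95 -
SLBB                 PF10531.14    50 WzaEc_like           -            175   1.1e-50  103.8   0.0   1   1   1.1e-50  1.05e-50  103.8   0.0     1    50   126   175   126   175 0.95 -
SLBB                 PF10531.14    50 WzaEc_like           -            235   2.9e-28   59.9   0.0   1   1   2.9e-28  2.93e-28   59.9   0.0     1    50   186   235   186   235 0.95 -
Wza_C                PF18412.6     35 WzaEc_like           -            280   4.2e-50  100.0   0.0   1   1   4.2e-50  4.15e-50  100.0   0.0     1    35   246   280   246   280 0.95 -
other                -             40 WzaEc_like           -            252   0.00046    6.6   0.0   1   1   0.00046  0.000458    6.6   0.0     1    40   213   252   213   252 0.95 -
Poly_export          PF02563.20    91 KpsD_like            -            115   2.6e-35   73.8   0.0   1   1   2.6e-35   2.6e-35   73.8   0.0     1    91    25   115    25   115 0.95 -
SLBB                 PF10531.14    50 KpsD_like            -            175   5.3e-48   97.1   0.0   1   1   5.3e-48  5.34e-48   97.1   0.0     1    50   126   175   126   175 0.95 -
SLBB                 PF10531.14    50 KpsD_like            -            235   1.8e-29   63.1   0.0   1   1   1.8e-29  1.79e-29   63.1   0.0     1    50   186   235   186   235 0.95 -
SLBB                 PF10531.14    50 KpsD_like            -            295   3.7e-33   70.0   0.0   1   1   3.7e-33  3.65e-33   70.0   0.0     1    50   246   295   246   295 0.95 -
GfcC                 PF06251.16   151 KpsD_like            -            456   5.2e-50   99.5   0.0   1   1   5.2e-50  5.17e-50   99.5   0.0     1   151   306   456   306   456 0.95 -
Wza_C                PF18412.6     35 KpsD_like            -            501   3.2e-45   93.3   0.0   1   1   3.2e-45  3.19e-45   93.3   0.0     1    35   467   501   467   501 0.95 -
Wza_C                PF18412.6     40 KpsD_like            -            265   0.00033    5.6   0.0   1   1   0.00033  0.000325    5.6   0.0     1    40   226   265   226   265 0.95 -
Poly_export          PF02563.20    91 WzaX_like            -            115     1e-12   31.6   0.0   1   1     1e-12  1.03e-12   31.6   0.0     1    91    25   115    25   115 0.95 -
SLBB                 PF10531.14    50 WzaX_like            -            175   1.2e-22   51.6   0.0   1   1   1.2e-22  1.16e-22   51.6   0.0     1    50   126   175   126   175 0.95 -
GfcC                 PF06251.16    40 WzaX_like            -             46   0.00042    7.2   0.0   1   1   0.00042  0.000421    7.2   0.0     1    40     7    46     7    46 0.95 -
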