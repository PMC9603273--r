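>MXAN_7418 synthetic stand-in beta-barrel query
MYVGRNTDAILTNAQNTDQQESVAEEPCITMNIRNAVKCQPYVFPIGPVMCLMICWDDFV
TAKTLIFRDCAMPAETCIDRPESKIFLSKRYWSKQEKVCYRKGQQTWLDGWGTVWPYVCT
PPYPIEGINCIESAKFWTFALENHEFARSEMYEKDIHWEPGIDVEVGNSVNDHNQGVSFV
AEYQPEAESQVCDKWMCQQEDCMYYEFGKIYDMHYLQAHNPFRGVNWGIACFYGSDDQKD
RSRYKIESAEDYLAFKYPQRKMTAWKNSFRIMYYMEHSENFFTCEMYATICPGCFICANS
SVHEHGDSSISPEMHCAQIMLEFNSGGHSRITRDMEPGQVENVCMREYDVCVNFPPAFGQ
SQNKWQFRQCHDFYHFIPGVKPVTAGEIFQFEGMYHIVFLPALDLRHISELNRLSAISMG
RRLRVKHRPN
>MXAN_3226 synthetic stand-in beta-barrel query
LRDIFIYFRWWVHKLQKHWSILCWLACWSQFWKVLLQGKAPSEWAWTCRKAPRQTYWKHH
PPRRPSHKCNYCASRWMATVVDRPLVYHLMCNFYPIWVPEYYFIFTATKNKSVGMNCHYE
KWAQRCVCIYMIPQMVIFTKNDEGARQDKDSLKRPSVNAYKDPELEVTDQNEWVQCQEAI
KMTVAYPALTGPERFMGGNPLEWQLHLRVGHFLILMHHFATWPRHGCPRTMYREFVQMQS
GSVWHGNSYYPKLYQIWVDQQLVTCMPPMHIMMYILSLLQQRVCIQPYWYNHCASRKDSC
DVESVIEALSAMSQQGRYNGIDFSILDILAHDRNKQDWSGPVVDMAGPVIWCWMMMCRYQ
YLPYIKNFCFGTNKVAICKLTQCAMTWKARCVHIT
>MXAN_1916 synthetic stand-in beta-barrel query
HIYCGFESVWDNVASGEWVIEFVNVPWWFEFFHINHAYFPDCSFPVEGSACTSFDESGLA
WTLVAGADLKRQYCYMHQRKCTHVWQGKDCVHCPADVHPFISAMKDLHSYTRWEYGCNMS
AIHITDGDYFNCRKRVFISYIQGWHCGFAHAVSMWCEWLYCLEDNAQYYTGMNYPQTYNE
SMDRTLKMPAEVHEPCEGVALWVEQTWVQKHFLYICEWFNGSPCDQCNGICPCYGSKTQM
ADPFRDFRWKMCMIFDVSIWEMQTRIWAKLRDFHSGITQDFFPLQSEPGTHRPGSPWKGT
AAMTVMAKELGGVKDPGWMRDGTIMFLNYADYPMEKVITFQRFGRSAYSYYWECDCQQLE
DQGRMFPMIGNICHQIWYSHFTVVRCPELDEGLGGIDVNSMQECEFQDDCYNNRGYVQER
WQKDSQWCQNECHIT
>PgaA_bb synthetic stand-in beta-barrel query
SAHNIVWHSPVEVIMVVAGTPYVFNRNCKYCDNATNAQSIGLDNLAKALMGHFCCKYGGN
SALFTAGSRAVRAKIRFSWQKVLAVYYLIQVLDVEKMLMYHANWRFPEECQKDYYKQECQ
PDLLFCKWCAIFATLVLHPENTCVYKQMWWLLVVCDRGGPFYSRRSQILIKNQWMRYILI
KECGMCFHAWHWREHHWDDLYVWIIVNSGNNFCISIHPICKAMGWTFCLTWEWHISAHQY
CQKEDTKENTCRMTFEWTPKTPHHHGITLYGSEPRNIALFYKHFYAQFNINCWGGPPFKP
KDDQFAESHCEFLVGHTKHFVVWKQGNWRSNASRHGSAWDRENWILHRTYLQSSMPMWNF
MWVQEVNKHPKRVYGNWYNTCMYWCKCDCGGQGDTQYFDFQTGFFSPPVFICVENDWHRE
PCSQFVPCMYPNFNNHHEKVFYGYGWAIRITQMGLRLDMYCSREAYPDYSAHYCDRVDWP
WYDTQTTLSFIRAVPRKMYCTKNFSEVQVRLRKLGKSQHHFYPVRKSTPGNISHCFKLYM
KDSCSYICSVKHTRMYIIGKVHWMTAAVSRMIYHFVVKHQDLMDNSCCEMGYVYDPTLFI
KCCNYTGNCANTCSWSMTYMCEMLSVQQCINMTAYEMCREWGFEAYFNANVCTSPVKPPP
DVMHPGREQVEVAGEATPKWEHDCKHTRDNSWHTRRSRWTQECESCPHMEHNDEFNPPCV
MMAKHIRSILAGAYIRFMCETISDEWTLKVTLSLNEPFPASFQRELRNDFSQGVLERHCD
CNWVKIEDRPPTCCIPLHVMYHVMWKH
>GfcD_Cterbb synthetic stand-in beta-barrel query
RQCDFMDLNFTWKEMSLMHGRVWLECEPNSFMNSDHGFEAQETHYREILVDSLFMPQTAA
KVKFMKCSMKRVDKKVIDTHHFMVNGWLMGGLRVSHAIARVAPMCHVTLWFFVYDAKTCC
WTDQNGSHQQVYYEHQIADYMDCQNHTRKDLFFGMRIERTLCWLSFMCQNFATHDEMFEW
DTMQPDYARHGISNHQIVWENMIQTFLPFEILSDTWAIPHFIRMCLLVLKGVKTLVEPTQ
HLICGPHPRGYPRFGHYYVVPCFDTMTLLKKTCLVARDCYIEGQLFLDVFTSIVSHYQMP
VWKAGDYAGHTMEMGGNFFLFFTYKCSLSGWPQQAVFAPQEGMNNDQIDFQIWQHDSSVL
TTREQDHMMADGLTNRIGCIGKLARAYCPGSQWPKDQFNSTFLCSNNIWDQICIIADCCT
MWKNTEQGVLEIPLSTCKQKNDRNSNVMAQADAQQPIPAGMQGWDFYLGYTHIFAAANTW
QADHGAIQVNKTYELIDSLLHTEDQWKMSWKYKDTDLTFQEYFDSWLGKLQTAWPCYKAC
NDRAQHDQFFNGEGVIMAAMMVDVWMKERQENIPRMNQPQEWPHPGVWTAITKWWYKYFK
SDKDKLIYQKFCEKAKRYRWVVWDDVAGFHLYMVKWFQYLLSTASSMIIIEGKHMWFQPI
PWRYHDCEAAFRMKVTVFFLNYPRHYPHDQLYPKDGPNDYGTAMKICYIALH
>YjbH_Cterbb synthetic stand-in beta-barrel query
QTLDPYMDLHPQLDKKPVYWRPDDGWIETREQDGCGWAAFLDSAVQDTAEHKVTGMQEPD
MSQTVDDNFPMFFPDMDNNFWYCSIWCKGRPIEFASIQSKEIMDRDIKASQLSSDQAMML
CYWAIVHPMQASYTYKGYYCMPRLTRLKDPSGKGAMRYYAMVCTAYEDQEKTWGEIDVSD
QFPCMTTSDQQFFITSEIPGRHRCCTCTYPMCQDCCRYPHGCGNGIIMCMGAIIFTKCFH
CFRCIHIGRKDEWDNRYHAEAEDPPPEADIVCWFATSVDKQNISYALSIVYDDRELENKL
DVKKNLAYIDKHSKLGRWKGREYTACVTDGPWRRPYPSCQRVVLADHHFREIHMVSFGIG
HLATHRESFTGTTRFVVTHYDEHHAGPQCPIQYQSNPLKAWLGLYMVERIIMFDFSWFFM
WGMFVAKHHDKQKRVWNILGCKNEEEPEMDNAQNWDEDQPDTSCPYTRQLKMMQMAVKED
VLIRNYPFDKPCMVHFDESCKQIWTYGNITNWYLNALDPRVSALNEGNLAGLCYQICMYW
YSWNMYASTIYDQSYACEGKMFSWCMVDQEYKSVEMWARSMQYNTSEGCKVEKPYEEVDD
RVGINTADTCFSSTDDDYQRQEVHRYMVYDWANDEQSGQGHPTDGEMVWGHWKNKTHMQH
HFGEPAEGVQHAEVLWHGLSSLPLKFPPYTCFGSFKHCDMNSLWQKTL
>BcsC_bb synthetic stand-in beta-barrel query
MILHTNGKRNLAKDQFALYPYCSWVMSVRCLRLMCLSHDKVFWVQFCVVHMFHKLPFCIQ
MKICRFTWYVQMAYSFSKCNSNGRPRVQQMKCMPCKIVDFETPHDEDKEDPDKRVRYWVY
FGYMVNHNGPQTPHNDTTYCQGDQFCESPNWRKGPASFRGMIHKCVSGHICSFTESMPYS
CQCCESGSYGDSYYSGPWCPRGYMMTTQRIIWRREGPSWLVAFENFSEFKIDGALYFQDI
AHGPAWNRCRSHIVHMSQLFRCRQQSCCYDLNKFSHPFFPNIVNDTTACNWPPQFRCNYF
EFTHADYWWRWMADRGAAFPLYSINLFLYYAQIHSRPANRMVHTDQYYCQIHPHLYGSQN
MPALPVGGMVSQAEHGQIHAITKRNRDFCKPMTRAAKQKLHSQHMSSDWMDFNYLFPIES
KLEADQLPEYPRNEYQSSFQFNNERVCKGRELNRPDNPQCDFECLFDWSSRYANFMGMKL
KWRLKRKEYNLPNGWSLHKSNDLATSMKQFKCEYDFRPCLFTWIEKLCEHKFTFQTVIPF
KARTWPTSVVWYPTAKSVCNCPWPHKSFPMNKASVCNDVSNHMQIARRGEMCQGDLGDFF
YWGNAEHMYATTTRYKFHMFKVVSWKMWRGMGSTHEGCVFSVNDFWWHLFKNSPPMLYLI
TAGDGLMTMQQYRQDDEDACDQHRCQTMKRQWVAQCNPKCDCSRKQEYEWRYAMQYQCHF
EFYDTAHNTFKYYNFMIYIRAINRWQAKRACRSAGTVQALNCREKQHLTHRDCLHHEIYC
KQQAWDPNQCVVPADNPWETMLMPSHMATPEMDGLKGIGIHNCSDRWIFEQWYSPMGNVA
LCNFMNDRKARPPNNTYWMQDWYKCVHYEVRGATCHQHEGMWAMYWIQDPVFWFQFLGTI
GCHWIYAKNECYIFTTDSNNQITDCGVYSGQAYTFWPICAHKCCIPLAMYANEDPHEAAT
KVEIMKGFWQEATMLTTDKIFDYFCISSCTKDQDCDLIDAHGCTCSMYYSAPPMYVQGLK
RMWDFVNWDHCPGTEKLWHHDSWDASTHVHDPWPQHHEESGPAQDKMKPRNVVYWDCKHA
WEWLVVGHMWHQQVYEPRGCNYKLMACVELPWGENVMYIMRFQMKTKNVNVVLVFCGKMR
MAQIWQIEQGLGFHIQP
>AlgE synthetic stand-in beta-barrel query
KPMTMLLYMLYNDWIDWLKLENLCCKFFPWAMRANGHLDHHSDHWWDEKAWNHWHVIMAL
GPSREYFMCFAQSYHVDHTKAHGPGMSSRGDGATQKEPYRDHYVSWSPGSNIRFWGMRWH
RRHPIAAPQIEYAFASGATDPDPGIWMGYDVCWVVGDNMTSHTRHQPQYKHPHMLWEFFY
NSPQPVQGRATVVSLVNAWDIPRKCCIPGYMMWEAFWCGNRPSHFLCGTHCCTHCTTLSR
MQRCTHVALPCDGKGFVWVYYYRYKLNLKITNHMQMVMYFFFKWGPLNRAQQQHREYILC
DWHPCPKVKVVDHTHILHGERVDNKCMWDWCKLIWIYLPKENNEYHSSHPYQNEQFEGDL
TLDGCCLCKYKQLWPTMRPWKRGNFITEKAKQCVELIYMSVPQMTRTSYFSRYVEPGFII
KNSHNADPPWGWFGIKANAKSFMLCPCVLRRIRHSWETDWCHMTVLSKGRKWCRHAGMGE
YCVVINEVRQ
>Wzi_bb synthetic stand-in beta-barrel query
RQQGSKVNDIDPMPPYSKLRWRVGRNEFKFFYAMVKQHYLIQCFLTKRFMDVMMNGFPEA
FIVARPMYAFYQDANLESYNCVKTKAWKGPKDNTMTTECGIKMWHHSICTWEFQQEWVRC
CRNATPKGVNQDFEESTQVFQAFANKLWERNEAEESEWTAFPEHYFNNGDKDMLYMYWNK
HRAVSQTIAINIASWADRMFQKEGQAFQMSLNRVFIKFWADMTHPDQGSYWQSMWNHVDE
YKNPNAENNMCRLWQWAPAACSMRHVVFALYHAKGPMRFCVSNFCAYWTVELEHCMGPQW
ALSGMVKEVEKTMTIAQLFENRMRCGQEHMEEPDHGMCYNCTIVEVVQWQLYCNIEAYPK
SVEKGNFSGQDVWAKDAFWHVVKASWQPTIYKVASGMRFLICNGCHKRVPELWKYPRTDF
HSKKQETGWWDHKACQHHKETERKGNVSIGIIEAPSPTRYTMNIHMSKNITFKTQRWQH
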