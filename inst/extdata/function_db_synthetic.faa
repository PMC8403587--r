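>core_PTase
NEMDASFTGPLVFNDFYEPAEKFPQDLCRWAPWPIQVPVGELGARGDKVLGSLKQDAYRPANEPTELHVM
GNDGWPEMGAVDSSQLQRSSWQFPLVACEDFNDCTQSEAVHNEGSTPPDRAAAEAEVTADQCPYDEEQHE
DIMVVKGHYVAVQSIPVYIGYGNQGRIWNALQKMRESQDEDMQPIGSSENIWENLFGTVIISSSLINTEI
IYEGIKYLLDMVLLLLFFETDMQDSDMRVCYVLRFHPTQA
>core_GGPPS
AFVLGTSKKEKDGSLSVTKEIQALTFLYGSSTTRENCESVTNRFGARKTHYYALFHVNNWGTTIFVGYLF
WGPYKVINEHAMPITATSVPLLHTETISLGYGVFKQVQFDILFGDLARTTPDVNNFYKEVQLAKFAALLC
PVADETAALGGRLSDPEESIADVYGKRISGRGVFPPVVAQEAYRANKADLFCFCNPQIVFFEWREGLLSG
CLKQPLTFLQEFARGEADRFPPEIPVYGYKGEVLGVSRLR
>core_FASalpha
ARIERFPEGEDEGASVRIACGNNFFANCIDFPAYVEKRGEKELAAFLHSDFGNFRTNIAEQLVISAGLLL
AGHQCRSGVSMRQGRVLTENRVISRNVAPQRNLGPITRMGAERGVQQTGRTQLPERKGGFYGSDGRDSLR
LTLPTTERTGVPKYGTHGCNARFRVSTFDYVKGSIPQKMKRVDAGLDKREAAGFPQQDMTGGVCPGVEAA
ANVRLHGSLESFVHDPARRCEFQRVMSGSTKKDRFDSSRVGAPEADNVSTAQGVPLHLIEIKGLPPVSNR
IFEELEYGNKREAIEDARNEDLGTESSISRNMGQENLELMDLHTCIDVASQSSGVIQPSLSEVSPKHLLE
GRLPLELSKGQKGIGAIWATYEQAQKFNHPMDSIAKWSTQFDLCAKVNNGPAVSSESEGSLLLWIMTELD
KVIKCRMHLVELPSFDDFMPKLKGDYWQGTPSVPCGETSDNGSSCFPEGIPNRRESIGAIQYSMYAESGV
DYSRNLGEKI
>core_FASbeta
TALMSLSIQVEPGAMKKFLGFFLPKAYQSYPSGIDILMFQRPRMATESRVIPELDRFPYEDPAFKVRRLG
SVMSIEGLEHGENCLDLTIQDQVMAAFTNYATASVEFVKLNLHRPMSVAKMDNAAGQKYQNGMLASNTLG
GAERPRTGRVGQSNKTRLMTVPPIGDLPLALGVPVSHFKQKGHAGAFIQQESTTGGPIIVAWLPRLRAYC
VDSQTVERTYQAAGTDALPSELDTHNELIGYHFFNKLLSLTKEAREFCQAVKLDRREFAFEGLGYVLPKG
EDVFQNLEERSTSLTQIYKQSDQGCLLRIETGTDARIKKEISDVTMVVFDFTEGNAGFMIGKKLKKLLNA
YEESVTTMASSFGVKQDGMDVSDGFDNAVSEHTKDSFLRLLKGLQEAPSSAAKFAMLLERQICQTEGACY
LRSKIDDEKFSDVPSGREITGTTAWRTLAT
>tail_p450
HDSMALEDAQLLRARSKLKIQWGTNKVVDPLGLASTYLSPAPYLDETQIVTEPNDTNGVERAHVPKVRLL
ARIVTEKKTLRLNKTTLDDSMRNFVNFKTSPGTSDKEEKQKLMKLSNMFYACTSRILEQTANSLPGTLFF
RIDGLSESGLSETRRAALHAPPVVSAVAVLVSFKEHKGPISGKFKDLRKWCAGEASVDAYATKRQDPDSN
VYYKCTSIIERVTVGTHDNVRIQEYILGHIGDDFFGCKKSASTCMAAIVILKPLAAKQELVNTGKARVRQ
FTVKKSTSQAVDDADRCNAVSACFMKDIIVASDHSPYLHG
>tail_fmo
RAQHLIISFVISLMGVKPCTNNAATIWATPIGKTDEETFDRWGPRKYKDARMINSLAHSRFDKKRPSNAN
TLQWCAALMNRLMYELGTEPLLHFPVGFEVQFINLRLTDITLTPDLEPRVSLTKVHPLLVFMVAKRRYDY
MYTDDQVQPQMDRLPTVPTIPQVQAACEGSVLTFKTDKADVYSHVYRLAAGDDKSGQASVKINKEFPDEP
VVNELVVDEGSYECLLNQVDHAPLALAVLFVDDQLFLTNPQAFAALIVELYIMPVTANYTQCCFAAPSQY
LDVSISELSYKARHENVSQP
>tail_omt
FRGPLFYPFTFGFLVSSESILPSLDTQTVCSMIFTLGKIHYGPQSFFNILLSEPEVALDAAEQEGEPQVK
LYSYFAMRAHRKNKSLIISNTRGVMQGVHVSKATFLIERETGKVWNKRQDSDRRSLFLVDTVGFRALVVP
EMFDGREEMSGLRGEAGFVMLPVVGHNPKVFIKVLGLDYRKSRWHIGVKELPAYFTKDAAPYSIFEPWDH
NGQDLNTALFACSGVTHASCLRNIVPTSQFTASSDQHIETSTKCRDETEF
>tail_gt
AINKEGTGDKDAYFEHTSSKSNRALTLGASAKGGRILVVVQAVNRGWIYAQSAKTQEIRYELCIQLPLKA
TNHTHVPFYWPLHQLPNTYKAMEFLKCKRAHGIYKYAGAMCPKLKVLAQASAEPNGQVGMEVFCGKDEFV
FKDSYQSNLRAEYRAFRELNQHRNAECRCEIRIGPMTLKDSWGGIRRPGAVDQAVLVYDAIRTLSRKDAP
SSLTYLAPTGAVSCESCSLTSAHPNIGDAPRPTSAEFKFKADQIIGNLDVGKGEHYGYLLASAVSLTGPQ
>reg_zn2cys6
FPSPGQPQKISTIATSLDVSRILMSRMRHMTMEDETFNDDERVGDETKLDIMQCNRKEETEFESGLLVLL
AEDGAHNNSDIVPNLSLLPFFKGIRAVAMEQEESYKAVQKRDIIMVLLTCDYQNYDLKQVMALASRMRAG
KEGIWKLQEPRNGDEKNDIQLSREPAIDEKVGVTGDHPKQGGPRIAYPGQAFPTKQLNVNDSSWPRTAEV
AISKEPSGNGKTAIDNQNSEPRLLDRHQEAPVRIEVLMVSQFELARKQVKIVSAAVESFFEQPKERRSTA
>trans_mfs
FLMTGAIFLTSMEDDQDVESGSDMSFVAGKSKVSTNNKLYVAILLTIGKTMFSWIEAAQQDTDKAWFPNA
VSYMVDRGNPVADLYQDIYQDLHINQELSFGSSPQGMNGPDALKDFCRDDLVPYGKNESGIGVKEGLPEG
AQEESVSPDRMFYRFPQSCQEDGSRNAALALEDGPGYGIFIRANKLYLGRSGMHAGSQAGNNKSAKRRGQ
DDLSNVRKFFSKAGKDLKCECDSFKPLISEHKLRVLETSGKELRERCSKWREEGKDEWLKSANTRTRIRE
EPALDLPDTKGRTLVFKLED
>trans_abc
ILLQNAGFIEKPTDAGCVHVEDLRRILGSPFDVEDQEDKFPVRSKKSFSKYFVQAGEPPNTHALFFLDHS
KGNCASMAAWYYSPQAITKGLVTVGEQNSLRKMIEFQGTRLTQGVLAGEEEIEEREVDQTKGLMKGHPED
PSAPASMKCLRAKLVHEYTLNSTLANPLLQPTLPVITARPKDGCSDAIRQPRGMGGPRAALLAISSQHSN
ARETSDGQVMRYAGYYGATMNQCDTVPLDLEDTFPGDGMALEFVYANTSDFSHCSCPRGFSKQHLAKFVR
SLKDSFMMGLHQAMEADEIDSRLDIVNILRIDINFVETDTCHVSQEIVKSIHFPTWALYLVLAPFGLNDT
>res_pump
LILFLFGFLWFPEKTYQKIMGHIRLRQFELVNNGDIAYAMGPHEAKDVREEFILLLIPLNSLSQLTFSTQ
GCRVFHLINSGAINCFEVFHTVKWEDTEMRKLGYIARTKQTRLVVGLLAIDAAIYDTWCVRALCGITNVA
AFLGPAFPTAPALHMDYNILTLWNLASVGFQAPRGPLGEAPSERVQRFPSGQPNNHLPQADEAMHAVHLH
YPLDLDCFNRPIIDIGGYVSIMAVVSFNAAYTGYIFETMGSEGNLSNSCRWANKHPLRYAFSDQPNAMED
CQVSVFVSPYGEGQDLTQLGTDYTDLLNQF
>hk_actin
SECSRVAQLPIARMKKYNQFIRSDFGITDAELLEPTNWPTAIMTQNRGEQSGWFDGDVHDTVDDRSLKVN
GLKPNRTVLHKEQILDGRSQVSGQLLVKPIEDPLKNCLRLIKAPSGYYLEHVAFPHRTCDLLWTAAPVNF
LRNTGPKKTALSGAKSQLWEARLDTEARTYQVSVELVLLDAAEAANCIFSIPPCNKSRCKVRKIAMLTQY
LVSNNYFQILELIGEAYATFTALSFARDIGFTNQGCLLHIVGYSVTFIADNAQRTLGQQCRFPVSAMVVE
>hk_tubulin
TGLDDRGLQNQVAVWIYQAQIQIGKSGARQREANPLQEYRATDCLDVDDESRGLLMLACHGGRGDTYRLM
FDDQSPGTVLNPDMGAASHMTSLVSEVQENSKFERGLGCVRCVLKRWPQAAITRHKGRSASLMLSSQQDG
VNGAESLTGPGLQILISISGQQDSVKRPFQSPLMWKLVRAVMEIQEGGEPARSPHDNEAARALNSPRDGK
NFSDAILDQKAGVVASIAIRLGTVYDKVEDGIVAPKYVWRALILVSGHVVGELIGFIKYCDQMCFLLSWV
DWRLDMCTNASADYPRGPWA
>hk_gapdh
RQSYVQGGSAYIKGGASQGREIRVGEGKAHITKSGKVYIIVYLGESEKMILEDRRPSFTVSIQAPVKTLT
NVHLGITLRIDKILTGRVVDQPEQRCCSSAIIPPMTHYYLRMLITSQKTSAAAMEEKKTEFQCPNAVKHM
GTASVAQKVKGPEPSDDANSQRYIDRGLEKLQFAEILFLLKGFVLECVFAGSGQFTSEKIELNLLEGYSC
YQHNAGPCDPNKEGLPYNMILQIEIANHFPGTEHNDNLVSPVAVEASFIL
>hk_rpl
ILGLIVDPAGDTPPVNTKNPLNHVVLVTTPMTSFKVIDDTEKHQLRVKVQPSLGGEKTKWQNGSKIDTIT
SEDGAQPIFNSITRLGSPRARQVLEVSPSAPEKSMKEMRIHHAELEFEWMVVEIIAVRINSAKLSMNEVV
NRTAPNANAITPAQRHTGNQGVPTQLSKEFPEFSNSKWHLSARLDTVLAFHILREGLQYRHEMRNDLGAG
RWWSGTNFAV
>hk_hsp70
LKVGLGFSHLAIPCVCPGNTLSDCKRFPVWYDKNLTHRPELANDVVYMGLEISLFRLASGLLSPIKLIWN
LHGALNSVGPGKQTRKVNAEITPYEQDNYAQSCHSYGDVQIAMKSANEILAVHDRGCALQRQTLMEDMDI
NEASTLLARGALFSTEVDDGYHTKPAEGAGAYAPTTYCASSHHGQGSIYKEGCQRVFNPNSTLQSLGWNY
PVSQDDLFGRNPYNHSKSESRRQREHYLQGSTHESRFLNAYPMLQLVKSRSNNNFPFDPKRVFLQGEPQA
AFPAIDAQKGDVLEDSIDNPQAIAQGSLDNDVVGATNVPS
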