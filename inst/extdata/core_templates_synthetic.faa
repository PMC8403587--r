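>APH07629
RHASKSLASQKRVPAQEMDQFQFMGIVDQQITYGRAANVRMLYPPSGSFSNLNQFARLKIDITDKAGEKL
FEARVFRALEGVPGEVPLYIRKDYVCYLIPLRGLYATGEEVELTGAPYTEDLYLADRLFLRSGPEQTYLE
AARKNVCRIFIADNRCLSSYQLGIKDGGREFVLRKILLYSVRRQEKWFKKIDLYESNRLCEMIGMPRGFR
LKFNCLSLTRCYETSSGHHSLDYTRSDISTYPHIQYHIFMIFSSNYEKSATKKINDETEDYNGHSTSVFK
RTTSLQFIGRLTAGTAGMMVFTLSKQGEFDHLGIKTGKKNIFVIQEINFKKASGLAGFFAAKEAEEGERR
ARETRFNGNELLPPGYDAESSKVKKWSAERHRKPSLMRTAMYRPQWVFTKNEALNAEEHVEHYYVAIEPI
ESKGQHLGLEQNYLSAELGRAIHSPGLDLVNYFTRPENWEKGRQEKKEDNPEKASLLFPKGGGSASEASL
SGAAADLAALIELRRLDLPMAWQIITSVSVTEVYFPTWPAKGEMEKHKRPQSPQIIGVGAEGDVLHKDID
IKALRFTECAEAHYTRSPKDRLPTPRHGCFRSHKLPLRKYNAKTDDDNRGATGDGQYTLALIKVLPYADV
PIHKFNDCGYTEGGFGQTPSVDIQTRPYNISDEQTAKVEVGLYWGYNHDTKQWFQGGFDDKYLVLTAGQC
PAHKFLEAHFANPELADGVVGKGINYLKRLAVMERSFIADSWEAAKGLSQADYQIFEGTYDTDESLMIPN
PLSNIHNILPLRERIANVLPKDFQCHAMEGMYPKLDCIIVFASAYAPDQGSLPQPAYEKKYGNKGLGAII
EEGQLDGSEEGVSELYFAAVELTASNNFPVGKMAAALHLGMCPFNFAAKRNGIEVNASKGEDEYGGDPGQ
DKSTKAKFTIDLDRVQKPEREYEATQCDLPSEPRERALTSAQPGGYKNVRNEIEDRSLPAEYWWSLCTEG
LDTAPDEDVAVDARPAALEGRGSLDVECWAYYNLQLMGFDVLQDGPRSLCKRAGPFNVQQIIGDELKNRV
VVLKSNAQALAIKDPFKTDNRLGASAIHCKTVAADQGNSILGNHAFVNSTLNQEDEGPNVQYAAGYYENQ
RKGQSSELARVRELPTAIKWKFWLPVTDEYFSELPKRNADANAPLPLDNWQVPITGIQIRGPAKMDPSEP
GFTQALSLAAFCLNSMSTRIKQGAQAALRPVIDAAFAPGPDEQGPIAEIHNVADLGDKDDFKAYRIPHPK
DEWKGGAQPTYDQQPTGVGLKKWLYANDGD
>XP_960427
KLRSLERHPIVLNHFVKTRSMEILPKFINAISIEAPPKMTPLIFRKAYSGDIIPGAPDCGGIAIKLGVSA
GGYPTRAGKDTAITQLPVLGATPCPAIASKYELGVGHSLRLSMLFILEQEIGIKMPVYQRMCKATPIRMQ
MAIACEGSLPYFDERAMEVRWAVADWRSLRNWGHLADPREGSQAACVFLKHEVAFWNRTVLLLDADLKEY
MMDVKKIGGTEEIHCKLYYLILMLDLASLFKDRPIYKPPSPVAVPKWNYLAMHKIEQGLPCAGVVRPQVM
GHLYILCVSDTHQRRLVTTGEDWCLLILARDAVGSELSARLYERVMSHKNPHEDTWLKTIVEFTDEVDKA
WMLGDAARCLNPLKARVVPIEAVLVAKIRS
>S3DQP3
PLKSVGVKGAVLQKKEGDACMDQEVEDKIGAGKSRSVTRVDMMQSKKLEFGLCDICCLPDTRPYGLSSVE
VYASNAQDGTLDDKLKLGPTSNDVQEATSKRLEPPRTKRANISDPRFTRPPEKTFFLQDKVIFMLKPFEK
DAKNPDVPTIGQPTIGPGPLQSREVTAFNLDGPNVSCLKGHAKYESPITACSRVVPMNDFYKRVDDPLIC
VATTHNTIRYEELHAVNIFEGVQESDWLDALIVIEAYPLIIPQAPGLLGDADGLLNDGFLKIGWKFSQDG
ERPYMAPILRDEARKAEGHLTNVLAKNQDVTFDNPSMQLNWELLCVGKIGNLFSTDYLVIYMNLERQPFV
AFYRNPRDSLVMNTGEAFESALGGSNIEGTGISDLYLKKTTTGCVPAEFY
>AHY23922
ETDSDLPSLPMKQPFMGDNSTMLDPEIEFDDDIFSIFVRKIKGMIKQAININSGSDDEEVAFRRSFNETH
PGREVIADIAISTKGPISGVITLNFLMAIVKSGESQIAQAFVDHGQQTVKSYSRPKLAFLAQGGVSNLVV
SKAPAAAPRKLSLATWDVTADLGDNELLFRQLPAIGPLFQVLKSGREQDKSEPNHWCKSCEFNGYYHERY
MGFARSNIVDEAFDIVQGRYLYPASKWGETSLFLAVDFII
>AWM95795
ETESDVPSSKLKQPFMGDPGTMLRSEIEMPDCINKIFARDIVGMLKQDINLDPGDDDEDLTLAESFSEFH
PDKEQLANVGFSMRGPIEGVITLNQPLSVVAGSEGQVTPAGVEHGQQTVKTYLRPRLAFLSGGGLSNLVS
FKAPAAAPQKIQLAPWDVTNNSGDNDLLFRQLPSIGELFQVVFDCDESDKSDPDHWCNSREFAGYFNDNH
VGFARSSILDETFEIVKGTYFYPAKKWGDLELFLEVDFHN
>Q6WP50
ETKSGIPSSDLSQPMMSDNGETLKSEIDLPDCIYIIFAGVIKNMLKQAINVNSGSQDEEITFARGFKETR
PDTPVIADVGISMRPPDRGVVTLNELMAIVKGGEGQVTPAFDIHGQQNVKSYSRPRLAALTGGGLSNLVS
FKYPAAAPERLRIESWGVVNNMGDEEKIKRQLQVIGPLFQVTLKSKESDRSPPDHWVKRAQKDGFFFEAY
MGFYRSSIVDEPFCIIKGDYFYTASKYGELEVFLEVDFTL
>QOE88883
KAKADLPSSPMSEPFEGDNGTKLKSEIEVPDCITIIFARLIKGMIKQSSNVNSGSEDDQLTFKKEFSETH
PDTEVILQVGISMRGPIRVLITLNNLMKILKGGEGELTPAFIEHGQQNVKSISMARLYRLTGGGLSNLMS
FKAAAAAEQKLRLAPWSLTNNPGDNEMLFRQLQAISPIFQVLLTGKEDDKSEPEHWSKSEEFDGYFHNRY
FGFARSSLHEQPFDIVPGEYLYTASAWAELELFFEVDFFL
>C9K2Q3
ETKSDVPSSPMKQPFLGDNGTKLNDEIAMPEPITIIFARLLKGMLKQTLNVNSGSFDEELTFARLFEQTY
PNTEVIADRGTSMRGGITGVITLNQIMEVVKGGEGQVTGAFVEHAQQNVKSYSRPRLAFLKGNFLSNLVS
FKAMAAAPQKLCLCPWDVLKNLRDTELLFRQLPAIGPLFQVLLSGKESDKSSPVQWCNSAEFDGYFHERY
MWFYRQQIVDEPSDIIKNDHFYPASKYGELELFPEVDFFLAFVLGTSKKDKEGSLSVHKEIQALTFLYGS
STTRQNCGSVTNRFGVRKQHYYAMFIVNTPGPTLYVGYLFWGPYKQLNEDAMPITATSVTLLHSETISMS
YGVFKQVQFDILFRDLARTTPDVNNFLKDLPLAKFHALICPVADETAALGGRLSDPEESIADLYGKRISG
RGVFPPVISQEAWRKNKADLFCFAQPQIVFFTSREGTLSGCLKQDLTTLNQFALAEHARFPPQIPMYGYY
GEVTGVSRLR
>A0A1B4XBG5
ETKSTAPSSPMKQDFMGDNETMLKEEISMLDCINNIFAPLIKGMLKQAINLRSGSEDEELTFARSFNEKH
DDTEVIADVGISMPGDSRGLITLNQLMAVVKAGEDQVTPAFVEHGQQNVKSYDRARLAGLTGGGLSNTMS
FKAPAAAEQKIRLSDWDVTNNLRDNELLFRNLPAIGPLFQVLLEGKEAFKQEPDHFCKSSEFEGYFNARY
NVFMRASIVDEPFEIMKGNYFYPASKWGELELFLEVDFFCAIVLGVKKKQKDAGLSVTKEIQALTFLYGA
STLRLNCESVTNRFGARKTHYYALFHVENKGTTIFDGYLFGGPYKAIEESAVPITATSVPLLHTETISVG
YGVFKQVQFDIIFGDLAKMAQDVNYFYQEVQLPKTAAILCPVAEEDAACGSRLSNPEKAIADKYGKGLSV
RNVFPPVVAQEAYQANKKDLFCFCNPQIVMFELREGLMSGCLKPTTTLLQEFARGEADRFPPEIPVYGYK
GEVLGISRLR
>B2DBF1
ERKSDVPSEPMKQPYMGSNGTQLKSAQEIPDCIRIIYAMLFKGMLKQAINVNSGSDDEEKTFFRSFSETH
PDTEKIADVGISMRGPIRVVPTLNSLMIIVKGGEGEVTDAFVEHGQQAVKSYMKPPLAFITGGGLSNLIN
FKAPPAASQKLRAAPWDVTNSLWDNELLFVQMPAIGPLFQTLCIGKESDKSEVDHWCWNAQFDGPFSESY
MGFGSSSIVDEPFDIVKGDYFYPASKEGEAELFLEVDMFLAFVLNASKRSKDGSLSVTKEGQALVFLYGA
DTTRENCESVTERFGAKKTHYYALKHVNNWGATIYMTFLWWGPDKVINEHAMPITAMTLPLLHTETITLG
YGVFKQVQFDILFGDMARTTLDVNNSYKELNLAKFGAEACPIADETQSLGGRLSDPEESLADVYGKRISG
RGVFDPVVLQEAYRANKADLFCFCNPQIVFFPWREGLLRACAHQPLKFLQEFARGEASLFPPEIPVYGIK
GKLNGVSVLS
>P38604
RDTGGWIEEKTESNGSTASKICQLLIFPYAKNVVLKLKVEAQDKNLPTLGPLVGELSCYVPGKKLSLTEM
NKPHVNSEPRAVAFEAGPEQFVSSGLEFVDEYDVVTPDKYGAGQYLGAARFKKLGSAGCLVPEVLNSILS
ILGEPALIFIYGKHPSPRACCKPMENDFQYVDDQSIDSGEDVDSEEVDGSNLTPAGKKFLQTIFLQLLGP
SYRRESMGDTTCNPPSSYGTIMRPGDRDQSTAKHHAQSAILLDWNGDIQLVQGAYAVGETRLRKGATVHI
HLAGAEHHKKAEDDKENKAQHSNWQAVPSEVGMTIGRDDMCRVEAEQFAMGEPREEAVLGYNPAPDLDQK
AVKGRLQYGEMQTLKIDHFVRAFMAKPLLRERLFSLHLCNYRGWFKIEET
>FernS
TNPPCGSDAVIAQAGERIHYGKFTSFGATLQALGGQRSAVNELHAENKVLSECKCEPQGDAQVSIGATKG
FVPGIVKTVLILVIERVGCSILYHMIAAYRWKPFLSVVVHETSTEGPSMTINKIINTFLANANSDVQPQE
LQQFLYLKTESSKLLANEWVFAGIKNCRAAIDIDPRELCMAVVMRFGGKLDLLLYTKTYTINNLTILQGW
RYSPTIASSSQSYATRGFGLLCYMTRQPSGSGQGFKLKDVANFNDVIANVGAQKKIFVCILYGSKAKVSR
ESHINRGMPGAILKEENNCRTAGRLAWELSHMKAIGQAKLSQIQYTLRYYIENAKSQINSIYGALENTQF
YSLPSVIKLYRNDEPTDNVCEPTETEIDAKSQDGLSDLNIGLAKGLAIPV
>QOV03404
NEKANPCIGTKGVGKFIKYIKSISDLCSRDAELASPKIRAMRDVKNQWLAATVANSELGLKKEFSTAEKP
DSEEVIDVAYGYGGKPFIELVSSAEGGEDLTQHKQTDFAGLTEKENLAIPNFNQLMLLWPNNNLAFLDCG
VVVLVTAVSSSNNMIVDLEDTETQSTSYPGFKANKDLAHFSAPEASRGTRATAEDCMTARDLDNMKEDLP
QSLSDREIIVENTMAHENTASGISSKLMLGATCIDVGHTKPFTPIPVGNMSTAEKSLGFKVMTTRDAAQV
TGYLDPMIPGPSVLENADWI
>D4D449
SLTGEKIQTIYRFWFETQPQEGAIGSPRDVRPENALAVEARRLLNDWDSALNRGCQNFDEMPESCSLAIQ
AAGGRYVCSGIPEDEVPEFNFMSRFKLLFITGDSSDLNTAESSELVQGVRAYKVSAIITNSITIEILPQL
YVENKLIEIVEYNDVGRAGFLLYLLEEREPGHASSEFKTCYFYSQLMLTVACGGKSSKEIQLAAGVRVPY
IQHNLEAPSEKSAPLDVWKVCLANHKGLEVAFAKALGIKVTQGGAQKSLYGARGVKTMNEVTLLNDDGRD
GTEASGMLTGQCGPEKRGAS
>AMR44282
QSWGSSYPIACRHYLPAYDLAKLTAGEHLPTVGALEGIWVAWTEDCAYGIRPEDRIIKPNHRAA
>OphMA
QTADKRPKFDGLLAQVEIGAMRKADVQRTNAQTKPANAMDVGAGVGEADEGAENYSWHTSKIWWLNMQPV
>ACB30126
NNNKDLCKNIALDGVIAKLAAFYLLASWKALQVCFRMNFKMDLAQVMHNAVGLSFPDE
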