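>SAT
RHASKSLASQKRVPAQEMDQFQFMGIVDQQITYGRAANVRMLYPPSGSFSNLNQFARLKIDITDKAGEKL
FEARVFRALEGVPGEVPLYIRKDYVCYLIPLRGLYATGEEVELTGAPYTEDLYLADRLFLRSGPEQTYLE
AARKNVCRIFIADNRCLSSYQLGIKDGGREFVLRKILLYSVRRQEKWFKKIDLYESNRLCEMIGMPRGFR
LKFNCLSLTRCYETSSGHHSLDYTRSDIST
>KS
YPHIQYHIFMIFSSNYEKSATKKINDETEDYNGHSTSVFKRTTSLQFIGRLTAGTAGMMVFTLSKQGEFD
HLGIKTGKKNIFVIQEINFKKASGLAGFFAAKEAEEGERRARETRFNGNELLPPGYDAESSKVKKWSAER
HRKPSLMRTAMYRPQWVFTKNEALNAEEHVEHYYVAIEPIESKGQHLGLEQNYLSAELGRAIHSPGLDLV
NYFTRPENWEKGRQEKKEDNPEKASLLFPKGGGSASEASLSGAAADLAALIELRRLDLPMAWQIITSVSV
TEVYFPTWPAKGEMEKHKRP
>AT
QSPQIIGVGAEGDVLHKDIDIKALRFTECAEAHYTRSPKDRLPTPRHGCFRSHKLPLRKYNAKTDDDNRG
ATGDGQYTLALIKVLPYADVPIHKFNDCGYTEGGFGQTPSVDIQTRPYNISDEQTAKVEVGLYWGYNHDT
KQWFQGGFDDKYLVLTAGQCPAHKFLEAHFANPELADGVVGKGINYLKRLAVMERSFIADSWEAAKGLSQ
ADYQIFEGTYDTDESLMIPNPLSNIHNILPLRERIANVLP
>PT
KDFQCHAMEGMYPKLDCIIVFASAYAPDQGSLPQPAYEKKYGNKGLGAIIEEGQLDGSEEGVSELYFAAV
ELTASNNFPVGKMAAALHLGMCPFNFAAKRNGIEVNASKGEDEYGGDPGQDKSTKAKFTIDLDRVQKPER
EYEATQCDLPSEPRERALTSAQPGGYKNVRNEIEDRSLPAEYWWSLCTEGLDTAPDEDVAVDARPAALEG
RGSLDVECWA
>ACP
YYNLQLMGFDVLQDGPRSLCKRAGPFNVQQIIGDELKNRVVVLKSNAQALAIKDPFKTDNRLGASAIHCK
TVAADQGNSI
>CMeT
MSRKVSDGKLWRNSSLEAIFEAYHSASSPTKIFFNALVNFRCGAIGAIKTQRTGLEDAEAGHYLVRALGT
RKVHQTERFAKAMMNFERIQDIGRGCDLTKFLSFCLMKTDQGIDKLGLTGKKLTPNIAGQDIDPTSVRCK
YVMGTPHSSFTISFERSNDVMLTTNMLHTKAAPAIEGGSPLSVWYSLDRILGGTALFNFE
>DH
ITHEAHFRFRQTGEGYGQDLSKVLRYDLLNVVAMVIDRPEKASLPRFGQIWKMLPESQRSALAPNSSANG
FGSAILYFSLTEQVVCLRREGQPLLMFITAGLKAPGRLVVVVQKSKVAKEYAEFDKACQDMWKLSHCDII
ANNSHGKWGEVGLTSRRFNKVGERAELPLWTAAINAQART
>ER
SLYCKIAFPGSGNNATNACLFDIANKQVKEGASAQSGILGANQMEAIKKHLDIFEALAMMVVVQLNNLNK
HVVHRLIVIELIVILIIAKLAGGVFLSYVKYGPYLCSTRLALSDGPTKEEFFYFVGAVARAGNLDKRRPN
KTENQERVPAEVDTPPARAKNALAMYTPNIHHLIFPWGGIHQGAENQYERCGLAEETKLHREIESTHDLV
VVKWMANERDYAWSLAQIFGTSDMGVKYELRLPPLFKGNR
>KR
EYLKSGNMNEVMPGGCGMGVFLGETLADEDVPWSYIVELLAGNVMHKECGSGDELTDNRAHKNGTECTLL
GGSDRKECATDLETYISVVHEFDTIVVMFKVSTVRYRKSVRIGDSKIAVGNIGITESAQTHIMSPLDKGK
IKKMNDKKAALEFEQFYENELSCTDRTIGAHFNSYSSEAVIGAPESWDGAVPSDCIFEKSTGATLTRVKK
GQDALIQTAN
>TE
LGNHAFVNSTLNQEDEGPNVQYAAGYYENQRKGQSSELARVRELPTAIKWKFWLPVTDEYFSELPKRNAD
ANAPLPLDNWQVPITGIQIRGPAKMDPSEPGFTQALSLAAFCLNSMSTRIKQGAQAALRPVIDAAFAPGP
DEQGPIAEIHNVADLGDKDDFKAYRIPHPKDEWKGGAQPTYDQQPTGVGLKKWLYANDGD
>R
DIYEMKDSAGMDTLSFSASNSLVARGLLLVKKKGPQTRRQVHFASRQGTKFVAGASSGHPQGVTVGFTKY
LENTTDQENLLAACGVDRLDSLLLDLQFGTTYIFTGALRLSAFPQCVLFFTHPSSALPDYALSMTSEDLR
DAMRMNWLLCGNFDADNPAISMSEQSGSSAKPSGIFDSYYDVAHVNQEDYFGEGVLLFISVAPALIQAWE
KAQPVDIQFKGKIIQHALLQLLSLMTSLNISTVPGLAGVH
>C
GEGKNTKGYKIKEVQGDIDGSYVAIVIPNNNSACQLENSSNTKLEALAGDYIRGVYQGLHIVWTEADESG
CRKAQKTYGLHVTASIENLMADFHGEQMGEIDDTNLFFAEILGNNRRFAGLTAAQSLRDFLQDRQFEFAE
VPAVWAVRARNEMPLPLWEFQVFPPSIEELNAQDPVLAPSLAGGYQSPWPIPVYNRGLVETVEKIYAIDA
QYCENSQLHGYGHATEHSNGYNWEPVICCKSKSISISKSVLKPKSPFSHFIRAGVLSGLQGISWDRVVFQ
NSPLAKGVGRAKNYGYDGET
>A
PLKSVGVKGAVLQKKEGDACMDQEVEDKIGAGKSRSVTRVDMMQSKKLEFGLCDICCLPDTRPYGLSSVE
VYASNAQDGTLDDKLKLGPTSNDVQEATSKRLEPPRTKRANISDPRFTRPPEKTFFLQDKVIFMLKPFEK
DAKNPDVPTIGQPTIGPGPLQSREVTAFNLDGPNVSCLKGHAKYESPITACSRVVPMNDFYKRVDDPLIC
VATTHNTIRYEELHAVNIFEGVQESDWLDALIVIEAYPLIIPQAPGLLGDADGLLNDGFLKIGWKFSQDG
ERPYMAPILRDEARKAEGHLTNVLAKNQDVTFDNPSMQLNWELLCVGKIGNLFSTDYLVIYMNLERQPFV
AFYRNPRDSLVMNTGEAFESALGGSNIEGTGISDLYLKKTTTGCVPAEFY
>T
FQHPDALAICIAWPLLPDFSRPSYLIIDYEAAEPLKIILMAMALTRLKTARKGANSLKEVGKVKRRLNQC
QDGNPWDTIR
>E
NDWLEGYGANAHQLSSRITKEINILNVSQENFGTVATDISQRGWDTMQITDGASNSLGLRRCMRNQTSID
NQELGTQIGTTVNGEPAQYLDMGYVNSYIGLAGTLSQDHLEQFYSSDTKPEKSFECWLVVESCTGCELLT
LVRSNQSDAAAPMRALYLSRLQDNYREHFNYGPALKRTRLLEVTTTEVASEYGCLTQGPYFPVKKHPPQN
GCNDKCGLIIAVCCSLRGELEDDQHNSGLENGWKAIGRYE
>GGPPS
AFVLGTSKKEKDGSLSVTKEIQALTFLYGSSTTRENCESVTNRFGARKTHYYALFHVNNWGTTIFVGYLF
WGPYKVINEHAMPITATSVPLLHTETISLGYGVFKQVQFDILFGDLARTTPDVNNFYKEVQLAKFAALLC
PVADETAALGGRLSDPEESIADVYGKRISGRGVFPPVVAQEAYRANKADLFCFCNPQIVFFEWREGLLSG
CLKQPLTFLQEFARGEADRFPPEIPVYGYKGEVLGVSRLR
>TC
ETKSDVPSSPMKQPFMGDNGTMLKSEIEMPDCINIIFARLIKGMLKQAINVNSGSDDEELTFARSFSETH
PDTEVIADVGISMRGPIRGVITLNQLMAIVKGGEGQVTPAFVEHGQQNVKSYSRPRLAFLTGGGLSNLVS
FKAPAAAPQKLRLAPWDVTNNLGDNELLFRQLPAIGPLFQVLLSGKESDKSEPDHWCKSAEFDGYFHERY
MGFARSSIVDEPFDIVKGDYFYPASKWGELELFLEVDFFL
>CS
NEKANPCIGTKGVGKFIKYIKSISDLCSRDAELASPKIRAMRDVKNQWLAATVANSELGLKKEFSTAEKP
DSEEVIDVAYGYGGKPFIELVSSAEGGEDLTQHKQTDFAGLTEKENLAIPNFNQLMLLWPNNNLAFLDCG
VVVLVTAVSSSNNMIVDLEDTETQSTSYPGFKANKDLAHFSAPEASRGTRATAEDCMTARDLDNMKEDLP
QSLSDREIIVENTMAHENTASGISSKLMLGATCIDVGHTKPFTPIPVGNMSTAEKSLGFKVMTTRDAAQV
TGYLDPMIPGPSVLENADWI
>FAS_alpha
ARIERFPEGEDEGASVRIACGNNFFANCIDFPAYVEKRGEKELAAFLHSDFGNFRTNIAEQLVISAGLLL
AGHQCRSGVSMRQGRVLTENRVISRNVAPQRNLGPITRMGAERGVQQTGRTQLPERKGGFYGSDGRDSLR
LTLPTTERTGVPKYGTHGCNARFRVSTFDYVKGSIPQKMKRVDAGLDKREAAGFPQQDMTGGVCPGVEAA
ANVRLHGSLESFVHDPARRCEFQRVMSGSTKKDRFDSSRVGAPEADNVSTAQGVPLHLIEIKGLPPVSNR
IFEELEYGNKREAIEDARNEDLGTESSISRNMGQENLELMDLHTCIDVASQSSGVIQPSLSEVSPKHLLE
GRLPLELSKGQKGIGAIWATYEQAQKFNHPMDSIAKWSTQFDLCAKVNNGPAVSSESEGSLLLWIMTELD
KVIKCRMHLVELPSFDDFMPKLKGDYWQGTPSVPCGETSDNGSSCFPEGIPNRRESIGAIQYSMYAESGV
DYSRNLGEKI
>FAS_beta
TALMSLSIQVEPGAMKKFLGFFLPKAYQSYPSGIDILMFQRPRMATESRVIPELDRFPYEDPAFKVRRLG
SVMSIEGLEHGENCLDLTIQDQVMAAFTNYATASVEFVKLNLHRPMSVAKMDNAAGQKYQNGMLASNTLG
GAERPRTGRVGQSNKTRLMTVPPIGDLPLALGVPVSHFKQKGHAGAFIQQESTTGGPIIVAWLPRLRAYC
VDSQTVERTYQAAGTDALPSELDTHNELIGYHFFNKLLSLTKEAREFCQAVKLDRREFAFEGLGYVLPKG
EDVFQNLEERSTSLTQIYKQSDQGCLLRIETGTDARIKKEISDVTMVVFDFTEGNAGFMIGKKLKKLLNA
YEESVTTMASSFGVKQDGMDVSDGFDNAVSEHTKDSFLRLLKGLQEAPSSAAKFAMLLERQICQTEGACY
LRSKIDDEKFSDVPSGREITGTTAWRTLAT
>PTase
NEMDASFTGPLVFNDFYEPAEKFPQDLCRWAPWPIQVPVGELGARGDKVLGSLKQDAYRPANEPTELHVM
GNDGWPEMGAVDSSQLQRSSWQFPLVACEDFNDCTQSEAVHNEGSTPPDRAAAEAEVTADQCPYDEEQHE
DIMVVKGHYVAVQSIPVYIGYGNQGRIWNALQKMRESQDEDMQPIGSSENIWENLFGTVIISSSLINTEI
IYEGIKYLLDMVLLLLFFETDMQDSDMRVCYVLRFHPTQA
>LSS
RDTGGWIEEKTESNGSTASKICQLLIFPYAKNVVLKLKVEAQDKNLPTLGPLVGELSCYVPGKKLSLTEM
NKPHVNSEPRAVAFEAGPEQFVSSGLEFVDEYDVVTPDKYGAGQYLGAARFKKLGSAGCLVPEVLNSILS
ILGEPALIFIYGKHPSPRACCKPMENDFQYVDDQSIDSGEDVDSEEVDGSNLTPAGKKFLQTIFLQLLGP
SYRRESMGDTTCNPPSSYGTIMRPGDRDQSTAKHHAQSAILLDWNGDIQLVQGAYAVGETRLRKGATVHI
HLAGAEHHKKAEDDKENKAQHSNWQAVPSEVGMTIGRDDMCRVEAEQFAMGEPREEAVLGYNPAPDLDQK
AVKGRLQYGEMQTLKIDHFVRAFMAKPLLRERLFSLHLCNYRGWFKIEET
>SHC
TNPPCGSDAVIAQAGERIHYGKFTSFGATLQALGGQRSAVNELHAENKVLSECKCEPQGDAQVSIGATKG
FVPGIVKTVLILVIERVGCSILYHMIAAYRWKPFLSVVVHETSTEGPSMTINKIINTFLANANSDVQPQE
LQQFLYLKTESSKLLANEWVFAGIKNCRAAIDIDPRELCMAVVMRFGGKLDLLLYTKTYTINNLTILQGW
RYSPTIASSSQSYATRGFGLLCYMTRQPSGSGQGFKLKDVANFNDVIANVGAQKKIFVCILYGSKAKVSR
ESHINRGMPGAILKEENNCRTAGRLAWELSHMKAIGQAKLSQIQYTLRYYIENAKSQINSIYGALENTQF
YSLPSVIKLYRNDEPTDNVCEPTETEIDAKSQDGLSDLNIGLAKGLAIPV
>DMAT
SLTGEKIQTIYRFWFETQPQEGAIGSPRDVRPENALAVEARRLLNDWDSALNRGCQNFDEMPESCSLAIQ
AAGGRYVCSGIPEDEVPEFNFMSRFKLLFITGDSSDLNTAESSELVQGVRAYKVSAIITNSITIEILPQL
YVENKLIEIVEYNDVGRAGFLLYLLEEREPGHASSEFKTCYFYSQLMLTVACGGKSSKEIQLAAGVRVPY
IQHNLEAPSEKSAPLDVWKVCLANHKGLEVAFAKALGIKVTQGGAQKSLYGARGVKTMNEVTLLNDDGRD
GTEASGMLTGQCGPEKRGAS
>GT
GNFHCDQWTVHLLGGAAKVIVEYCHRTILDYAWADQQGPKEIRAKTDDGVMENLRCGEVAALTNVLEAML
SDVGETHFQSSLKAIGHTDPSKDTAIVVSLSFVGFLAVTFIYPRTPPQRIEGGKDKIWRKLVQNAERIEE
MAEAPSQVNRTLNNDALQLQMQKQIHFLLDDASEFEEDFRDGTPFQVYGVAATDEDVNISDRIQDSNGLP
KNGGIAFDHLQGDQPAQHIIFQFNVDTIGGVVWPLIVWGY
>CDPS
DYFIAFNDEAKVADSQGRIGQRLTRIQKTDGTQVAQDSCQPLLTRVEVSHEIQQLELDLRLSSLNGCADS
SFKGTIVDNSLPLIDATLDSKGIGLPFACPVFIKSPRLAWMTTAWGADRHVNFMNKGGAGLLGPNTIWLD
LKKEMSYYAQGYLVNGYYRVPIAHVMVFRSTYIQLHILMNGITCAPRKNKIEYQVFIFDH
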