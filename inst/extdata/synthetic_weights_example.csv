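probe_id,effect,chrom,pos
cgs2885231,-0.000554836125182961,chr15,11751116
cgs5954668,-0.0380156915890359,chr15,117001018
cgs8696095,0.058789962583812,chr10,234093792
cgs2873658,0.120722485451738,chr8,135400440
cgs6380376,-0.0979256384113066,chr10,44819870
cgs9568335,0.07367949467149,chr8,135676814
cgs6030446,-0.0237441980749365,chr16,129247701
cgs7362540,0.0490585491892937,chr1,172964090
cgs8982454,-0.091217760976828,chr20,138407514
cgs9514878,-0.0130305408676134,chr5,98167078
cgs2171869,-0.047942265628683,chr10,183405833
cgs6593036,-0.0245147855033262,chr11,218660566
cgs3615973,-0.0538648356800328,chr21,91297142
cgs3081251,0.0184712955272223,chr1,136177279
cgs0748803,0.0608133240569675,chr18,115312497
cgs3961444,-0.0246921617807052,chr22,205697189
cgs0516082,-0.0113892360488594,chr22,39270904
cgs4288685,-0.0555824443523637,chr3,107054140
cgs5366505,0.0497916544704812,chr21,52020706
cgs3224446,0.0280914445473044,chr3,44041915
cgs6612293,-0.0782139278257939,chr2,98945897
cgs4396352,0.0740538509552655,chr13,71304643
cgs6190865,-0.0584602575056117,chr12,87451751
cgs8890761,-0.0526006768733178,chr7,222176862
cgs3988381,-0.0735922762414512,chr13,147265102
cgs6874726,-0.0596718460382093,chr15,135951207
cgs2029135,-0.0173989712345968,chr1,47431584
cgs4192833,0.0266411271574709,chr14,102661429
cgs0243933,-0.0355494287925421,chr4,70888076
cgs4546417,-0.00994945688162018,chr3,120141865
cgs1447169,-0.0140686661759232,chr16,62277424
cgs1060436,0.0585463137602489,chr7,57304073
cgs6658917,0.114436659296,chr5,18353533
cgs7378723,-0.0534428307249538,chr9,139554066
cgs9690575,0.0953102094281211,chr21,84364068
cgs1314101,0.106589885923943,chr6,209241746
cgs0181790,0.0115728181507676,chr18,139942639
cgs8168562,0.0448472868913598,chr11,176640897
cgs3348434,-0.086939635617576,chr19,200045978
cgs2097428,0.0234423970067766,chr4,189752222
cgs6914588,-0.0272073836598869,chr9,202589063
cgs1332770,-0.00827070769042235,chr13,120605501
cgs9348155,0.0276083281286407,chr19,24130682
cgs3674913,0.0516665105801748,chr8,189571841
cgs0789612,-0.00230894023917728,chr2,134844060
cgs1162540,0.131935365629789,chr2,37029287
cgs3153122,0.0294502874612509,chr12,886354
cgs5010122,-0.0101188667114606,chr5,149140954
cgs6035771,0.0220780069001191,chr22,97416773
cgs5749262,-0.00501288510414172,chr22,5813978
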