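>UTIL_TRYP1 Trypsin placeholder fragment 1 (synthetic placeholder)
QPYQDWYSKVTLPFWQWENDVYLPPDMGRKGRMACYTMLALEENWLWKLADRRHSQEMIR
DGYPNIYAGTEPWFQAPESS
>UTIL_TRYP2 Trypsin placeholder fragment 2 (synthetic placeholder)
ESYDEYIRDDRKSRTYSFEMIWDFDQIQGTMYVHIPDSCSQRSSLKQWGASFHTYDNHTL
SPCQDPKTEKYQQKAYTTVW
>UTIL_TRYP3 Trypsin placeholder fragment 3 (synthetic placeholder)
CEDMRHPLSALYTFEGGHKTWQTMCTVCHPCYWPRLDFMHVMTTKYTKRNWNCFLTWDKW
EYNLLWSYFNFCKHTLIGAESKSK
>UTIL_TRYP4 Trypsin placeholder fragment 4 (synthetic placeholder)
QTWYVSSTKTHVWFLTPLAACMVQRWVMHFVYYLKHSHGPPTKKDGSQPGSNHATPNEPI
TMYEPTMRRRHKQSDILDRSYPIYGITKGAQANGWQAKFIHIPSTSWAVRWEPLVPGQCI
ANDTHFRGSPIWRAGCHLD
>UTIL_TRYP5 Trypsin placeholder fragment 5 (synthetic placeholder)
MGGAAKIITQNSRFAGKYLCHEYVKGLWQSDCMMNDECGSRFRGAANLKLFSFMKNDEFG
FEEKHDFEASKDCGGQAVKRVTSLQCVNMGRSHIPPWAMYDILNRFQGWKQFAPCKDRIE
FKARMCITKAMFFMKL
>UTIL_CHYM1 Chymotrypsin placeholder fragment 1 (synthetic placeholder)
EVKWFVAHAWKSPEQGDERMPYKIDDWYMFMLPDYPWMAICSPKKREEEEHWMHAMLTCW
PRIQISGEHYLNYPGTLFLQRFTEK
>UTIL_CHYM2 Chymotrypsin placeholder fragment 2 (synthetic placeholder)
WQSNRFSQLWKISSCAHLNEAQQAKGMMADLFSNYHGCYWKRWKSPTQFTIRENATMVKV
EYGVANGYSQDFEFVHNFEPVWLVTWEAFTVYHPEQVVFDYSNRFTGNCGEVVMNVSW
>UTIL_CHYM3 Chymotrypsin placeholder fragment 3 (synthetic placeholder)
TDTYARHYLAQGLNGSSWGKMVPYVNWSDPKERHPAYRDSRYWLSVCMWMCQERNWAHTP
IDDDSEAAWSGNFWLFQSIQSMKAGW
>UTIL_ARGC1 Arg-C placeholder fragment 1 (synthetic placeholder)
WPKNNWELRVAPYVEMMINPVTKLLHCVYGPSYTNCLLRHDKWENADLLGAAKVPGGELD
YYRHQQPHGQWIVRNCMCQWPDTVSDFNVYCSQYYICHMKMYECDNDLTWIWMTWGI
>UTIL_ARGC2 Arg-C placeholder fragment 2 (synthetic placeholder)
SIGVVMIIPIPRGKLCKWMRFYEDTGESYNHWFWDFKHQHIRRFNSRNQNCTNYSEFICT
CFRKTILWAEWILDQTTMKKCMNDW
>UTIL_ARGC3 Arg-C placeholder fragment 3 (synthetic placeholder)
VDAKQDNMHSADHQAFWDIWSQFQCVCMVNTSIYPHSDQQWRDLYHYCNPLKTSQFNQKW
GLWRKHLWTIFLPTFADPCALEVSFEYKYYLYPADCDTLHNPVGFEDDVVKMKADVLPET
SYTCERQNSIRSQYC
>UTIL_LYSC1 Lys-C placeholder fragment 1 (synthetic placeholder)
QESCANHMIIPKHGNDYNDYPPNVNCKPDIHFYKKVDACMNDVPWWQYCGNMKNTDMDMC
WISFTEVATNMEKCASGHPFTFAIAKTTEWVHSAATYHIACIWVDAWIDTTQNDGRECFY
CWKMCNRHHTK
>UTIL_LYSC2 Lys-C placeholder fragment 2 (synthetic placeholder)
DERYAERRRDEYDHIAVHQFISKIYPQPGHKFAGGWFWPRFPVWKTLTCNFQGGVYIPWW
HFEQYGMCKAICFNGQKKIASCCVGCFTSSRPGVYGIEFQSKQVTDYART
>UTIL_LYSC3 Lys-C placeholder fragment 3 (synthetic placeholder)
YRDMDQAKFREDNWSYALQGDKCAETIVHFMWAHNMDFTIMQAFVIILIQSVCYDNHSPM
VQWFGPWTCVQQNEDQPQEMPMWPREMKFMHSRLVCKNSIYWCIHYGHECEDTNAAMNNN
FFCHWEVGQG
>UTIL_ASPN1 Asp-N placeholder fragment 1 (synthetic placeholder)
GLGMCQRCENIFGDPEIVSWWILTAGTRPELNNACAIRGDHFLFPTLGFGWQRVDPGQPH
LNPMPRLQMVHIQTGLISQEVI
>UTIL_ASPN2 Asp-N placeholder fragment 2 (synthetic placeholder)
HSGNQFRTQTEHHTGSCYNGLKHNTGIYWTNNSIMGMTCMHHQNEEIGYTFQIENLAHHM
VVRLFVVDRCFKCENTIELFFFEGEMVTNRNGSPFPKAFFMDC
>UTIL_ASPN3 Asp-N placeholder fragment 3 (synthetic placeholder)
TIVTCVSQMSSFYETPYMTCIWLPWSLKLGTMKAIHVSSRYYLEVADNSWWFKMVFAEDN
QGPPTCNTGEQENQGNCQPQDQMIQANGMDKAFIGCRHTTQQVMRGVVTESSWPNHMLRQ
LTDFVQL
>UTIL_ENO1 Yeast enolase placeholder 1 (synthetic placeholder)
YDWHDVQDQWACAWCECEDCWGPMVPAPKVHLQKNIQFYCCNRPEPGRSQRVYTDSDNAS
CTMSAELIKPAEYSFWHLQSTCYILDIPRVYEDSTDIKQTTRENRLTITESKGTVERIV
>UTIL_ENO2 Yeast enolase placeholder 2 (synthetic placeholder)
HNEDCVSFEVEDFANWMQRHYNPNESSVCTQYAKVHMFVQAIFIWIMHVWTDRSNVIDDY
QVWGCNGVYHMPHIKWVDSVKHLSKKTYYSHEDGCDPENPMQDAYPIILWGGATGPNPF
>UTIL_ENO3 Yeast enolase placeholder 3 (synthetic placeholder)
MFNACNMHMGNSLEKLCQWMTYCCVMTRRDGSMAPPGSQQMWNYQGGLVEKANLAGVLDQ
LQDSFANLCHEMLRPKKCTWIFLSKRMNNENYEEAHQQMKIMTYGYYDGDGMSMCQQCTA
MMGKHHGAESEYTAKVQKFC
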