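# Synthetic two-factor CFA oracle fixture.
# Covariance of simulated indicator data; oracle values estimated with
# the lava package (v1.8.1), ML, unit factor variances.
n 1000
p1 7
p2 9
oracle_phi 0.4996960212
oracle_chisq 102.03457943
oracle_df 103
oracle_cfi 1.00000000
oracle_tli 1.00019374
oracle_rmsea 0.00000000
oracle_srmr 0.01823779
0.93246429573166134 0.4554639616475038 0.46689499870039941 0.47969202197355154 0.48983998607622942 0.47582788243970453 0.49863584002693873 0.23698626006078058 0.29277389897853245 0.28522934679549772 0.18776668171001282 0.26941091407461998 0.2725318269519843 0.24590927287488346 0.27068373236963583 0.27359867149395894
0.4554639616475038 1.0488520757521422 0.54991535706511119 0.49041599085549537 0.50145478019677059 0.53106108180925093 0.49251699073081046 0.24666035087922764 0.28027262592961749 0.25549193620351146 0.23428566632738204 0.23074271275977182 0.27062124618317712 0.22298424557990346 0.22775800091127155 0.26778955794868464
0.46689499870039941 0.54991535706511119 1.0656151928247592 0.51494300598982701 0.50977475288537311 0.49930573937395611 0.500668166068715 0.18687130946234098 0.29741405871547832 0.24746722219111353 0.19732387627570044 0.26586864482882944 0.23219334664975308 0.24256132673405503 0.22225074629108113 0.27110092212499454
0.47969202197355154 0.49041599085549537 0.51494300598982701 1.0065741222816917 0.48844602852849489 0.51389660748081734 0.50601044322848254 0.25089483723244504 0.25403898697026395 0.26450151075331096 0.23938217856570354 0.25487567579094367 0.2625935127618782 0.24824573536255012 0.25200908314167064 0.28307766725488698
0.48983998607622942 0.50145478019677059 0.50977475288537311 0.48844602852849489 1.0014389757609095 0.5172128127443345 0.50004144946037221 0.28173780196567827 0.31129853749350328 0.23980842284896539 0.23932537407781587 0.25629368304874189 0.2883818267222048 0.26040249616586097 0.26603775281802933 0.28637318578470328
0.47582788243970453 0.53106108180925093 0.49930573937395611 0.51389660748081734 0.5172128127443345 0.99506536564112158 0.50797747107140101 0.22008284631347597 0.27549523632551604 0.23929382164060919 0.21504743654342348 0.29087680656697718 0.23890089884884846 0.24186473759909227 0.25494690255668401 0.26454549914235381
0.49863584002693873 0.49251699073081046 0.500668166068715 0.50601044322848254 0.50004144946037221 0.50797747107140101 1.0254284673596195 0.23877742362182869 0.29936521361939611 0.26329958009090759 0.25577765404295971 0.26110180588045606 0.3036049429155418 0.25700550995430055 0.27243159143141993 0.25582887842697122
0.23698626006078058 0.24666035087922764 0.18687130946234098 0.25089483723244504 0.28173780196567827 0.22008284631347597 0.23877742362182869 1.2355545545545545 0.46132132132132131 0.48132432432432432 0.43088088088088089 0.5135375375375375 0.52986486486486484 0.47781281281281279 0.51677077077077072 0.50774474474474474
0.29277389897853245 0.28027262592961749 0.29741405871547832 0.25403898697026395 0.31129853749350328 0.27549523632551604 0.29936521361939611 0.46132132132132131 1.2416416416416416 0.56398398398398397 0.49349349349349347 0.49005005005005003 0.57347347347347344 0.45835835835835836 0.52428428428428431 0.5553353353353353
0.28522934679549772 0.25549193620351146 0.24746722219111353 0.26450151075331096 0.23980842284896539 0.23929382164060919 0.26329958009090759 0.48132432432432432 0.56398398398398397 1.2513223223223224 0.48713713713713713 0.51224024024024029 0.58357857857857853 0.52552052052052056 0.56360160160160155 0.57726626626626631
0.18776668171001282 0.23428566632738204 0.19732387627570044 0.23938217856570354 0.23932537407781587 0.21504743654342348 0.25577765404295971 0.43088088088088089 0.49349349349349347 0.48713713713713713 1.2647647647647648 0.48568568568568571 0.53078078078078084 0.52677677677677681 0.52022022022022019 0.54589589589589593
0.26941091407461998 0.23074271275977182 0.26586864482882944 0.25487567579094367 0.25629368304874189 0.29087680656697718 0.26110180588045606 0.5135375375375375 0.49005005005005003 0.51224024024024029 0.48568568568568571 1.2499539539539539 0.5637237237237237 0.54270270270270271 0.53932332332332333 0.53949149149149145
0.2725318269519843 0.27062124618317712 0.23219334664975308 0.2625935127618782 0.2883818267222048 0.23890089884884846 0.3036049429155418 0.52986486486486484 0.57347347347347344 0.58357857857857853 0.53078078078078084 0.5637237237237237 1.3050800800800801 0.59637137137137142 0.55566566566566566 0.5637687687687688
0.24590927287488346 0.22298424557990346 0.24256132673405503 0.24824573536255012 0.26040249616586097 0.24186473759909227 0.25700550995430055 0.47781281281281279 0.45835835835835836 0.52552052052052056 0.52677677677677681 0.54270270270270271 0.59637137137137142 1.239014014014014 0.53464464464464467 0.52172672672672671
0.27068373236963583 0.22775800091127155 0.22225074629108113 0.25200908314167064 0.26603775281802933 0.25494690255668401 0.27243159143141993 0.51677077077077072 0.52428428428428431 0.56360160160160155 0.52022022022022019 0.53932332332332333 0.55566566566566566 0.53464464464464467 1.2472112112112113 0.5357777777777778
0.27359867149395894 0.26778955794868464 0.27110092212499454 0.28307766725488698 0.28637318578470328 0.26454549914235381 0.25582887842697122 0.50774474474474474 0.5553353353353353 0.57726626626626631 0.54589589589589593 0.53949149149149145 0.5637687687687688 0.52172672672672671 0.5357777777777778 1.2433943943943944
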