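afghanistan
africa
alabama
alaska
albania
algeria
america
amsterdam
argentina
arizona
arkansas
asia
athens
atlanta
australia
austria
baghdad
baltimore
bangladesh
barcelona
beijing
belgium
berlin
bolivia
boston
brazil
britain
brooklyn
brussels
bulgaria
cairo
california
cambodia
canada
caribbean
chicago
chile
china
cleveland
colombia
colorado
connecticut
copenhagen
croatia
cuba
cyprus
dallas
delaware
denmark
denver
detroit
dublin
ecuador
egypt
england
ethiopia
europe
finland
florida
france
georgia
germany
ghana
greece
guatemala
haiti
hawaii
helsinki
honduras
houston
hungary
iceland
idaho
illinois
india
indiana
indianapolis
indonesia
iowa
iran
iraq
ireland
israel
istanbul
italy
jamaica
japan
jerusalem
jordan
kansas
kentucky
kenya
kabul
lebanon
libya
london
louisiana
madrid
maine
malaysia
manhattan
maryland
massachusetts
memphis
mexico
miami
michigan
milan
minneapolis
minnesota
mississippi
missouri
montana
morocco
moscow
mumbai
nairobi
nashville
nebraska
nepal
netherlands
nevada
nigeria
norway
ohio
oklahoma
oregon
oslo
ottawa
pakistan
paris
pennsylvania
peru
philadelphia
philippines
phoenix
pittsburgh
poland
portland
portugal
prague
romania
rome
russia
rwanda
sacramento
scotland
seattle
seoul
serbia
singapore
somalia
spain
stockholm
sudan
sweden
switzerland
sydney
syria
taiwan
tennessee
texas
thailand
tokyo
toronto
tunisia
turkey
uganda
ukraine
utah
venezuela
venice
vermont
vienna
vietnam
virginia
wales
warsaw
washington
wisconsin
wyoming
yemen
york
zimbabwe
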