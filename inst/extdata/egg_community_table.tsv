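family	taxon	level	May	June	July	August	September
Cyprinidae	Pseudohemiculter dispar	species	+	+	+	+	
Cyprinidae	Squaliobarbus curriculus	species		+		+	
Cyprinidae	Ctenopharyngodon idella	species		+			
Cyprinidae	Xenocypris spp	genus		+			
Cyprinidae	Zacco platypus	species				+	
Cyprinidae	Pseudolaubuca sinensis	species	+				
Cyprinidae	Squalidus argentatus	species	+	+	+	+	
Cyprinidae	Gobiobotia meridionalis	species	+	+	+	+	
Cyprinidae	Onychostoma gerlachi	species	+	+		+	
Cyprinidae	Garra orientalis	species		+			
Cyprinidae	Sinogastromyzon wui	species	+				
Botiidae	Sinibotia pulchra	species		+			
Botiidae	Sinibotia robusta	species			+	+	+
Mastacembelidae	Mastacembelus armatus	species	+	+	+	+	
Serranidae	Siniperca scherzeri	species				+	
Gobiidae	Rhinogobius spp1	genus		+	+	+	
Gobiidae	Rhinogobius spp2	genus			+		
	Unknown species 1	unknown			+		
	Unknown species 2	unknown			+		
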