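{"LF_M_01":{"dam_id":"LF01","group":"LF","sex":"M","body_weight":30.0273133392041,"k1":0.0405526891811494,"kL":0.0109976715761606,"k2_true":0.0187240941433245,"pool_volume":6.00546266784082,"fasting_glucose":7.73234959488843,"egp_basal":0.144781241763788,"egp_suppression_depth":0.558600015053157,"egp_tau1":40,"egp_tau2":10,"ins_C":1.59490293988274,"ins_ke":0.0118875346983927,"ins_ka":0.050471922057172,"ins_baseline":0.322900365731984},"LF_F_01":{"dam_id":"LF01","group":"LF","sex":"F","body_weight":19.3421053371409,"k1":0.0364870558367106,"kL":0.00838155473164738,"k2_true":0.0203062700339947,"pool_volume":3.86842106742818,"fasting_glucose":9.8930135141908,"egp_basal":0.200890203869117,"egp_suppression_depth":0.461055012304825,"egp_tau1":40,"egp_tau2":10,"ins_C":1.73448253377899,"ins_ke":0.0113203486079115,"ins_ka":0.0522305963400187,"ins_baseline":0.451411042158335},"LF_M_02":{"dam_id":"LF02","group":"LF","sex":"M","body_weight":29.0962409924147,"k1":0.0325859757640996,"kL":0.0107150247188088,"k2_true":0.0202941526002985,"pool_volume":5.81924819848295,"fasting_glucose":7.25789247876778,"egp_basal":0.147292777520672,"egp_suppression_depth":0.482889022415034,"egp_tau1":40,"egp_tau2":10,"ins_C":1.55037304920745,"ins_ke":0.0130393581926429,"ins_ka":0.0532875966043751,"ins_baseline":0.556410988439518},"LF_F_02":{"dam_id":"LF02","group":"LF","sex":"F","body_weight":24.0251320966898,"k1":0.0324504754924675,"kL":0.00917962943357064,"k2_true":0.0184459464896444,"pool_volume":4.80502641933796,"fasting_glucose":7.81431563084954,"egp_basal":0.144142447979842,"egp_suppression_depth":0.337548835826883,"egp_tau1":40,"egp_tau2":10,"ins_C":1.02447056091731,"ins_ke":0.014108478877068,"ins_ka":0.0461597366105716,"ins_baseline":0.392338689706335},"HF_M_01":{"dam_id":"HF01","group":"HF","sex":"M","body_weight":23.0364412267945,"k1":0.0414789547902154,"kL":0.00893864245191155,"k2_true":0.0203710939183551,"pool_volume":4.60728824535889,"fasting_glucose":9.19944759087676,"egp_basal":0.187402810870736,"egp_suppression_depth":0.558792208694058,"egp_tau1":40,"egp_tau2":10,"ins_C":1.23929172254779,"ins_ke":0.011544010059605,"ins_ka":0.049484308628378,"ins_baseline":0.357537513633148},"HF_F_01":{"dam_id":"HF01","group":"HF","sex":"F","body_weight":19.4571670148532,"k1":0.0338519848181743,"kL":0.010147867824811,"k2_true":0.0192812416191598,"pool_volume":3.89143340297065,"fasting_glucose":6.70991226937457,"egp_basal":0.129375439709176,"egp_suppression_depth":0.551108056642716,"egp_tau1":40,"egp_tau2":10,"ins_C":1.74933991080087,"ins_ke":0.0125619490976941,"ins_ka":0.0559287607030534,"ins_baseline":0.403511467983947},"HF_M_02":{"dam_id":"HF02","group":"HF","sex":"M","body_weight":26.807002171056,"k1":0.0327510642792611,"kL":0.00923753368359238,"k2_true":0.0184232732501849,"pool_volume":5.36140043421119,"fasting_glucose":8.59047131312383,"egp_basal":0.158264600349555,"egp_suppression_depth":0.494345270191807,"egp_tau1":40,"egp_tau2":10,"ins_C":1.68326861815561,"ins_ke":0.0121729826013735,"ins_ka":0.0539639923241112,"ins_baseline":0.405357740633294},"HF_F_02":{"dam_id":"HF02","group":"HF","sex":"F","body_weight":22.0745126103737,"k1":0.0435199921879938,"kL":0.0100209331648187,"k2_true":0.0252660612738825,"pool_volume":4.41490252207473,"fasting_glucose":9.2785388696832,"egp_basal":0.234432131613516,"egp_suppression_depth":0.493727399918295,"egp_tau1":40,"egp_tau2":10,"ins_C":1.40201610656789,"ins_ke":0.0115239998047982,"ins_ka":0.049543108497039,"ins_baseline":0.486335161897854},"GDM_M_01":{"dam_id":"GDM01","group":"GDM","sex":"M","body_weight":22.8546534574256,"k1":0.0469126552951239,"kL":0.0111432349439293,"k2_true":0.0210089611975559,"pool_volume":4.57093069148511,"fasting_glucose":7.47054256505791,"egp_basal":0.156948338873991,"egp_suppression_depth":0.39153136564551,"egp_tau1":40,"egp_tau2":10,"ins_C":1.21482459885885,"ins_ke":0.0125261616215182,"ins_ka":0.0509003104080233,"ins_baseline":0.457650581951466},"GDM_F_01":{"dam_id":"GDM01","group":"GDM","sex":"F","body_weight":20.4728129602383,"k1":0.0411903654107264,"kL":0.0112039885639772,"k2_true":0.023211770834498,"pool_volume":4.09456259204765,"fasting_glucose":6.21217370695989,"egp_basal":0.144195552470047,"egp_suppression_depth":0.466469187863082,"egp_tau1":40,"egp_tau2":10,"ins_C":1.13916521729743,"ins_ke":0.0129086044324423,"ins_ka":0.0509176790502892,"ins_baseline":0.226847786757359},"GDM_M_02":{"dam_id":"GDM02","group":"GDM","sex":"M","body_weight":27.6815062442805,"k1":0.0507571801509164,"kL":0.0110071168204992,"k2_true":0.0192926969517198,"pool_volume":5.53630124885611,"fasting_glucose":7.24265575769271,"egp_basal":0.139730362658794,"egp_suppression_depth":0.524876947886618,"egp_tau1":40,"egp_tau2":10,"ins_C":1.03835378517668,"ins_ke":0.010909072049395,"ins_ka":0.0442307749494139,"ins_baseline":0.326454983053837},"GDM_F_02":{"dam_id":"GDM02","group":"GDM","sex":"F","body_weight":22.7433266258093,"k1":0.0414430510235315,"kL":0.0111243077195921,"k2_true":0.0209960177886888,"pool_volume":4.54866532516185,"fasting_glucose":6.52202546318276,"egp_basal":0.136936562643267,"egp_suppression_depth":0.412450030614294,"egp_tau1":40,"egp_tau2":10,"ins_C":1.20764175062217,"ins_ke":0.0118296643683638,"ins_ka":0.0511693636094036,"ins_baseline":0.420431190343956}}
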