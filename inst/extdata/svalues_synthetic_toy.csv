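phantom,source,target,s_mGy_per_MBq_h
toy_3organ,heart_wall,heart_wall,2.0
toy_3organ,lungs,heart_wall,0.3
toy_3organ,remainder,heart_wall,0.05
toy_3organ,lungs,lungs,1.2
toy_3organ,heart_wall,lungs,0.25
toy_3organ,remainder,lungs,0.05
toy_3organ,heart_wall,liver,0.1
toy_3organ,lungs,liver,0.15
toy_3organ,remainder,liver,0.06
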