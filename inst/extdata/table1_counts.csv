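site,traditional,maft
neck,2,1
shoulder,9,11
elbow_wrist,2,7
chest_back,1,1
lumbar_sacral_hip,7,9
knee,11,6
ankle,4,3
forearm_ulnar,0,1
sternoclavicular,0,1
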