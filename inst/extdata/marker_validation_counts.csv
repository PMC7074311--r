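material,marker,tp,fp,fn,tn
varieties_209,e7_VviAGL11,48,0,0,161
varieties_209,5U_VviAGL11,48,10,0,151
RGxAR,e7_VviAGL11,13,1,4,30
RGxAR,5U_VviAGL11,13,1,4,30
RGxRS,e7_VviAGL11,29,1,1,17
RGxRS,5U_VviAGL11,29,1,1,17
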