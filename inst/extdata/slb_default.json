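{"f_min":100,"f_max":500,"anchors":[0.241,0.385,0.443,0.557,0.9],"segments":[{"from":0,"to":0.227,"f_start":100,"f_end":100},{"from":0.227,"to":0.241,"f_start":100,"f_end":180},{"from":0.241,"to":0.385,"f_start":180,"f_end":180},{"from":0.385,"to":0.443,"f_start":180,"f_end":500},{"from":0.443,"to":0.557,"f_start":500,"f_end":500},{"from":0.557,"to":0.571,"f_start":500,"f_end":130},{"from":0.571,"to":0.9,"f_start":130,"f_end":130},{"from":0.9,"to":0.914,"f_start":130,"f_end":100},{"from":0.914,"to":1,"f_start":100,"f_end":100}]}
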