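{"models":[{"label":"bright-peach","p0":[255,114,90],"p1":[102,29,23],"radius":29},{"label":"dark-peach","p0":[190,54,44],"p1":[62,11,10],"radius":24},{"label":"yellowish-peach","p0":[126,88,42],"p1":[255,204,111],"radius":34},{"label":"brownish-peach","p0":[74,35,20],"p1":[206,113,71],"radius":21},{"label":"leaf-bright","p0":[120,216,88],"p1":[35,80,24],"radius":27},{"label":"leaf-dark","p0":[9,32,7],"p1":[65,128,49],"radius":18},{"label":"grass","p0":[152,193,90],"p1":[52,75,30],"radius":21},{"label":"branch","p0":[123,93,63],"p1":[40,29,17],"radius":17},{"label":"trunk","p0":[91,70,51],"p1":[19,15,11],"radius":17},{"label":"soil","p0":[64,52,35],"p1":[168,137,98],"radius":18},{"label":"sky","p0":[238,250,255],"p1":[115,124,133],"radius":22}],"fruit_labels":["bright-peach","dark-peach","yellowish-peach","brownish-peach"]}
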