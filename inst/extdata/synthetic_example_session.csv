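session_id,coder_id,code_id,start_s,end_s
example,coder1,3,0,10
example,coder1,1,0,25
example,coder1,5,35,50
example,coder1,1,40,65
example,coder1,6,55,100
example,coder1,4,55,60
example,coder1,10,55,70
example,coder1,7,70,110
example,coder1,2,70,150
example,coder1,8,110,115
example,coder1,3,115,135
example,coder1,10,185,220
example,coder1,12,215,220
example,coder1,10,220,230
example,coder1,11,235,240
example,coder1,3,245,250
example,coder1,8,270,280
example,coder1,2,280,285
example,coder1,10,285,285
example,coder1,2,290,290
example,coder1,4,290,300
example,coder1,8,295,300
example,coder1,3,295,295
example,coder2,1,0,25
example,coder2,5,35,50
example,coder2,10,55,75
example,coder2,2,65,150
example,coder2,7,80,105
example,coder2,8,105,115
example,coder2,3,115,135
example,coder2,9,135,145
example,coder2,5,135,150
example,coder2,11,150,180
example,coder2,3,150,155
example,coder2,10,190,225
example,coder2,12,215,225
example,coder2,10,225,240
example,coder2,11,235,245
example,coder2,3,245,255
example,coder2,9,255,260
example,coder2,10,270,270
example,coder2,8,270,275
example,coder2,10,285,285
example,coder2,2,285,285
example,coder2,2,290,290
example,coder2,3,290,300
example,coder2,4,295,295
example,coder3,1,0,25
example,coder3,1,0,15
example,coder3,1,30,50
example,coder3,10,55,70
example,coder3,4,75,80
example,coder3,8,95,120
example,coder3,3,120,130
example,coder3,9,135,145
example,coder3,10,145,180
example,coder3,10,185,210
example,coder3,6,225,240
example,coder3,3,245,255
example,coder3,8,270,275
example,coder3,2,280,285
example,coder3,2,285,290
example,coder3,10,285,285
example,coder3,3,295,295
example,coder3,4,295,300
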