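time,event
30,1
67,1
79,0
82,0
95,1
148,1
170,1
171,1
176,1
193,1
200,1
221,1
243,1
261,1
262,1
263,1
399,1
414,1
446,1
446,0
464,1
777,1
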