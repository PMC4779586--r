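class,walk_forward,walk_left,walk_right,upstairs,downstairs,run,sit
walk_forward,125,4,5,5,1,0,0
walk_left,6,125,2,2,5,0,0
walk_right,2,3,134,0,1,0,0
upstairs,10,6,3,116,3,1,1
downstairs,1,3,4,4,127,1,0
run,0,1,0,0,3,136,0
sit,1,0,0,1,0,0,138
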