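speaker_id,grid_id,n_sentences,removed_full,used_full,removed_aligned,used_aligned,train,validation,test
1,S1,1000,11,989,11,989,692,99,198
2,S15,1000,164,836,164,836,585,84,167
3,S26,1000,16,984,71,929,650,93,186
4,S6,1000,9,991,9,991,693,99,199
5,S7,1000,11,989,11,989,692,99,198
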