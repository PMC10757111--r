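patient_id,disease_stage,iss,age,gender,ecog,fish_high_risk,hyperdiploid,light_chain,pfs,event,best_response,cd3,cd4,cd8,cd19,nk
P01,NDMM,III,63,male,1,1,0,kappa,16.7,1,<VGPR,68.2,34.1,25.3,7.9,11.2
P02,NDMM,II,58,female,0,0,1,lambda,28.3,0,>=VGPR,71.5,38.0,28.9,9.1,14.8
P03,NDMM,I,49,male,0,0,1,kappa,35.1,0,>=VGPR,66.0,33.2,26.4,8.4,13.0
P04,MGUS,,71,female,1,0,0,none,40.0,0,,64.7,36.5,22.1,6.2,10.5
P05,NDMM,III,66,male,2,1,0,lambda,8.9,1,<VGPR,58.9,30.8,18.5,5.8,8.1
P06,RRMM,II,60,female,1,0,0,kappa,12.4,1,<VGPR,61.3,31.9,20.2,6.9,9.4
P07,NDMM,I,55,male,0,0,1,kappa,31.0,0,>=VGPR,69.8,35.7,27.6,8.8,13.9
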