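dataset,model,k,ll,n
bilateral_fof,full_9param,9,-1102.5,1809
bilateral_fof,sho_only,1,-1221.6,1809
bilateral_fof,lambda_only,1,-1121.1,1809
unilateral_fof,post_cat,1,-1963.1,3836
unilateral_fof,gain,1,-2013.1,3836
unilateral_fof,shift,1,-2217.4,3836
unilateral_fof,noise,1,-2272.7,3836
unilateral_fof,eight_param,8,-1957.5,3836
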