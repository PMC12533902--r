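# White-box tests exercise a few internal entry points directly.
cilad_forward <- cardiopipe:::cilad_forward
cilad_backward <- cardiopipe:::cilad_backward
softmax_ce <- cardiopipe:::softmax_ce
ppo_policy_new <- cardiopipe:::ppo_policy_new
policy_forward <- cardiopipe:::policy_forward
ppo_grads <- cardiopipe:::ppo_grads
nutri_state_features <- cardiopipe:::nutri_state_features
feasibility_mask <- cardiopipe:::feasibility_mask
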