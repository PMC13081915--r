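method,pred,tp,fp,fn,gt
two_step,6384,6303,81,361,6664
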