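sample_id,printed,recomputed,concordant,note
3,fp,"fl,fp",0,"mean SMI 2.95 and d_cube 186.6 um satisfy the literal fl rule, yet the published table flags fp only; the original analysis presumably applied a precedence rule or per-object evaluation that is not documented"
15,ch,ns,0,"the only ch sample; its printed mean volume gives d_cube 361.6 um and d_sphere 448.6 um, both under the 500 um cut, so ch can only have fired on the largest single object, whose diameter is not recoverable from the published per-sample aggregates"
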