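# Default Chinese negator inventory for negation reversal.
# One token per line; '#' lines are comments. This list is a pragmatic
# default, not a claim about any particular corpus analysis.
不
没
没有
无
非
未
别
勿
莫
不会
不要
不能
很少
难以
毫不
并非
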