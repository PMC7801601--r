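drug	dose	response
drug1	0.176776695296637	0.178488828359135
drug1	0.353553390593274	0.235967904677644
drug1	0.707106781186548	0.401583813533711
drug1	1.4142135623731	0.60761348797346
drug1	2.82842712474619	0.741499693697879
drug1	5.65685424949238	0.847613444902244
drug2	1.76776695296637	0.165601423353487
drug2	3.53553390593274	0.289702801756083
drug2	7.07106781186548	0.390054130445046
drug2	14.142135623731	0.576334201210685
drug2	28.2842712474619	0.735245171387514
drug2	56.5685424949238	0.849969331334744
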