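taxon,char,old,new,note
UFSM_11505,1,?,1,previously unknown cranial scoring
UFSM_11505,12,?,0,previously unknown cranial scoring
UFSM_11505,13,?,0,previously unknown cranial scoring
UFSM_11505,31,?,1,previously unknown cranial scoring
UFSM_11505,35,?,0,previously unknown cranial scoring
Aetosauroides_scagliai,5,0,1,surangular tuber present
Aetosauroides_scagliai,19,1,0,parietals wider than frontals
Aetosauroides_scagliai,30,0,1,dentary tapers to an acute point
Aetosauroides_scagliai,35,0,?,maxillary tooth crown state unobservable
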