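{"id":"doc00001","text":"patient smokes one pack per day. rislun lunris tammer yambal helpor helmer","label":"smoker"}
{"id":"doc00002","text":"heavy nciotine dependence noted. rismer lunbal demris zorlun gormer finbal","label":"smoker"}
{"id":"doc00003","text":"no smoikng after age forty. prinal pridem porgor merpor","label":"non-smoker"}
{"id":"doc00004","text":"tobacco use daily for many years. torris wexlun sulris helpor helmer merbal","label":"smoker"}
{"id":"doc00005","text":"uses cigrettes regularly","label":"smoker"}
{"id":"doc00006","text":"tobacc use daily for many years. yamdem lunbal camdem sulris","label":"smoker"}
{"id":"doc00007","text":"heavy nicotine dependence noted. camgor sulpor prigor risbal","label":"smoker"}
{"id":"doc00008","text":"tobacco: no. risgor tormer tamnal demlun zorpor cammer merpor","label":"non-smoker"}
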