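((((((Dmel:5,(Dsim:2,Dsec:2)simsec:3)melsimsec:8,(Dyak:11,Dere:11)yakere:2)melsub:17,Dana:30)melgroup:5,(Dpse:2,Dper:2)obscura:33)melobscura:15,Dwil:50)Sophophora:10,((Dmoj:40,Dvir:40)mojvir:5,Dgri:45)DrosophilaSubg:15)root;
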