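aic,atc,agent,role,brand_status,formulation,days_per_package
034561017,L04AD01,CsA,CNI,brand,,30
034561029,L04AD01,CsA,CNI,generic,,30
036782014,L04AD02,TAC,CNI,brand,IR,30
036782026,L04AD02,TAC,CNI,brand,ER,30
036782038,L04AD02,TAC,CNI,generic,IR,30
036782040,L04AD02,TAC,CNI,generic,ER,30
033123011,L04AA06,MMF,antimet,brand,,30
033123023,L04AA06,MMF,antimet,generic,,30
020421015,L04AX01,AZA,antimet,brand,,30
020421027,L04AX01,AZA,antimet,generic,,30
038415012,L04AA18,EVE,mTOR,brand,,30
036934010,L04AA10,SIR,mTOR,brand,,30
042123016,L04AA28,BELA,other,brand,,30
010112011,H02AB07,PRED,steroid,brand,,30
010113013,H02AB04,MPRED,steroid,brand,,30
010114015,H02AB06,PREDNISOLONE,steroid,brand,,30
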