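method,band_index,rank
Boruta,8,1
Boruta,12,2
Boruta,4,3
Boruta,6,4
Boruta,5,5
Boruta,11,6
Boruta,2,7
RFE,8,1
RFE,12,2
RFE,4,3
RFE,7,4
RFE,1,5
RFE,5,6
RFE,11,7
Stepwise,8,1
Stepwise,6,2
Stepwise,5,3
Stepwise,4,4
Stepwise,7,5
Stepwise,2,6
Stepwise,11,7
Lasso,6,1
Lasso,5,2
Lasso,4,3
Lasso,8,4
Lasso,3,5
Lasso,7,6
GA,4,1
GA,6,2
GA,7,3
GA,8,4
GA,12,5
GA,15,6
GA,16,7
GA,17,8
RelativeImportance,8,1
RelativeImportance,12,2
RelativeImportance,6,3
RelativeImportance,4,4
RelativeImportance,7,5
RelativeImportance,5,6
RelativeImportance,3,7
RelativeImportance,13,8
PLSR,4,1
PLSR,8,2
PLSR,5,3
PLSR,15,4
PLSR,10,5
PLSR,18,6
PLSR,7,7
PLSR,12,8
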