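method,band_index,rank
Boruta,12,1
Boruta,11,2
Boruta,9,3
Boruta,10,4
Boruta,8,5
Boruta,1,6
Boruta,2,7
Boruta,5,8
RFE,12,1
RFE,11,2
RFE,9,3
RFE,10,4
RFE,8,5
RFE,1,6
RFE,7,7
RFE,15,8
RFE,2,9
Stepwise,12,1
Stepwise,7,2
Stepwise,2,3
Stepwise,1,4
Stepwise,9,5
Stepwise,5,6
Lasso,2,1
Lasso,5,2
Lasso,9,3
Lasso,7,4
Lasso,12,5
Lasso,11,6
Lasso,1,7
GA,1,1
GA,9,2
GA,12,3
GA,11,4
GA,7,5
GA,8,6
GA,5,7
RelativeImportance,11,1
RelativeImportance,12,2
RelativeImportance,10,3
RelativeImportance,9,4
RelativeImportance,8,5
RelativeImportance,6,6
RelativeImportance,5,7
RelativeImportance,3,8
RelativeImportance,2,9
PLSR,5,1
PLSR,7,2
PLSR,1,3
PLSR,6,4
PLSR,4,5
PLSR,8,6
PLSR,15,7
PLSR,13,8
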