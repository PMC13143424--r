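FC5 -0.75646880044391 0.342798105731476 0.55699588208699
FC3 -0.543523304109841 0.362291155963971 0.757183951361762
FC1 -0.283942950358492 0.35069925312423 0.892404860363177
FCz 0 0.309016994374947 0.951056516295154
FC2 0.283942950358492 0.35069925312423 0.892404860363177
FC4 0.543523304109841 0.362291155963971 0.757183951361762
FC6 0.75646880044391 0.342798105731476 0.55699588208699
C5 -0.809016994374947 0 0.587785252292473
C3 -0.587785252292473 0 0.809016994374947
C1 -0.309016994374947 0 0.951056516295154
Cz 0 0 1
C2 0.309016994374947 0 0.951056516295154
C4 0.587785252292473 0 0.809016994374947
C6 0.809016994374947 0 0.587785252292473
CP5 -0.75646880044391 -0.342798105731476 0.55699588208699
CP3 -0.543523304109841 -0.362291155963971 0.757183951361762
CP1 -0.283942950358493 -0.35069925312423 0.892404860363177
CPz 0 -0.309016994374947 0.951056516295154
CP2 0.283942950358493 -0.35069925312423 0.892404860363177
CP4 0.543523304109841 -0.362291155963971 0.757183951361762
CP6 0.75646880044391 -0.342798105731476 0.55699588208699
Fp1 -0.293892626146237 0.904508497187474 0.309016994374948
Fpz 0 0.951056516295154 0.309016994374948
Fp2 0.293892626146237 0.904508497187474 0.309016994374948
AF7 -0.559016994374947 0.769420884293813 0.309016994374947
AF3 -0.294292017086073 0.830961619830334 0.472117564858963
AFz 0 0.809016994374947 0.587785252292473
AF4 0.294292017086073 0.830961619830334 0.472117564858963
AF8 0.559016994374947 0.769420884293813 0.309016994374947
F7 -0.769420884293813 0.559016994374947 0.309016994374947
F5 -0.618731272867559 0.619752696108508 0.482781739134701
F3 -0.433027429173862 0.645416362854495 0.62922568617528
F1 -0.222818402619442 0.63455567819109 0.740061518206133
Fz 0 0.587785252292473 0.809016994374947
F2 0.222818402619442 0.63455567819109 0.740061518206133
F4 0.433027429173862 0.645416362854495 0.62922568617528
F6 0.618731272867559 0.619752696108508 0.482781739134701
F8 0.769420884293813 0.559016994374947 0.309016994374947
FT7 -0.904508497187474 0.293892626146237 0.309016994374948
FT8 0.904508497187474 0.293892626146237 0.309016994374948
T7 -0.951056516295154 0 0.309016994374948
T8 0.951056516295154 0 0.309016994374948
T9 -1 0 6.12323399573677e-17
T10 1 0 6.12323399573677e-17
TP7 -0.904508497187474 -0.293892626146236 0.309016994374947
TP8 0.904508497187474 -0.293892626146236 0.309016994374947
P7 -0.769420884293814 -0.559016994374947 0.309016994374948
P5 -0.618731272867559 -0.619752696108508 0.482781739134701
P3 -0.433027429173862 -0.645416362854495 0.62922568617528
P1 -0.222818402619442 -0.63455567819109 0.740061518206133
Pz 0 -0.587785252292473 0.809016994374947
P2 0.222818402619442 -0.63455567819109 0.740061518206133
P4 0.433027429173862 -0.645416362854495 0.62922568617528
P6 0.618731272867559 -0.619752696108508 0.482781739134701
P8 0.769420884293814 -0.559016994374947 0.309016994374948
PO7 -0.559016994374948 -0.769420884293813 0.309016994374947
PO3 -0.294292017086073 -0.830961619830335 0.472117564858963
POz 0 -0.809016994374947 0.587785252292473
PO4 0.294292017086073 -0.830961619830335 0.472117564858963
PO8 0.559016994374948 -0.769420884293813 0.309016994374947
O1 -0.293892626146237 -0.904508497187474 0.309016994374948
Oz 0 -0.951056516295154 0.309016994374948
O2 0.293892626146237 -0.904508497187474 0.309016994374948
Iz 0 -1 6.12323399573677e-17
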