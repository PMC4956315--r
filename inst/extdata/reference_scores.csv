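dataset,image,acc,sn,sp
DRIVE,1,0.966,0.719,0.986
DRIVE,2,0.963,0.784,0.980
DRIVE,3,0.965,0.735,0.990
DRIVE,4,0.959,0.704,0.984
DRIVE,5,0.954,0.697,0.978
DRIVE,6,0.970,0.720,0.992
DRIVE,7,0.956,0.704,0.982
DRIVE,8,0.962,0.782,0.975
DRIVE,9,0.955,0.800,0.966
DRIVE,10,0.963,0.716,0.984
DRIVE,11,0.968,0.753,0.985
DRIVE,12,0.961,0.729,0.982
DRIVE,13,0.961,0.776,0.978
DRIVE,14,0.959,0.718,0.978
DRIVE,15,0.959,0.821,0.970
DRIVE,16,0.958,0.726,0.977
DRIVE,17,0.965,0.754,0.985
DRIVE,18,0.953,0.808,0.964
DRIVE,19,0.956,0.760,0.977
DRIVE,20,0.962,0.718,0.989
STARE,1,0.942,0.714,0.961
STARE,2,0.943,0.601,0.968
STARE,3,0.916,0.833,0.922
STARE,4,0.813,0.868,0.810
STARE,5,0.952,0.750,0.972
STARE,6,0.962,0.806,0.974
STARE,7,0.955,0.840,0.966
STARE,8,0.961,0.796,0.974
STARE,9,0.955,0.829,0.966
STARE,10,0.961,0.775,0.977
STARE,11,0.964,0.650,0.988
STARE,12,0.971,0.834,0.982
STARE,13,0.957,0.701,0.982
STARE,14,0.958,0.715,0.983
STARE,15,0.954,0.770,0.972
STARE,16,0.941,0.645,0.974
STARE,17,0.967,0.806,0.983
STARE,18,0.976,0.604,0.996
STARE,19,0.924,0.858,0.943
STARE,20,0.945,0.766,0.961
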