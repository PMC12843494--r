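data_regime,model,balanced_acc,ani_acc,ani_to_bac,ani_to_fun,bac_acc,bac_to_ani,bac_to_fun,fun_acc,fun_to_ani,fun_to_bac
raw,gcn,84.31,93.64,3.58,2.78,74.10,12.63,13.27,85.18,8.71,6.11
raw,last_ffn_svm,84.03,92.70,4.07,3.23,74.31,12.31,13.38,85.07,8.77,6.16
raw,last_ffn_xgboost,84.14,93.83,3.45,2.71,74.10,13.16,12.74,84.48,8.61,6.91
cleaned,gcn,83.55,83.41,9.01,7.59,78.45,4.78,16.77,88.79,3.19,8.02
cleaned,last_ffn_svm,82.12,79.76,8.55,11.68,76.33,4.25,19.43,90.28,2.23,7.49
cleaned,last_ffn_xgboost,82.43,81.44,9.72,8.84,78.87,4.25,16.88,86.98,2.92,10.10
pretrained,gcn,86.01,74.78,10.08,15.14,88.97,1.78,9.25,94.29,1.50,4.20
pretrained,last_ffn_svm,84.45,71.66,11.13,17.21,86.48,1.42,12.10,95.20,0.60,4.20
pretrained,last_ffn_xgboost,85.56,73.00,11.76,15.24,89.68,1.07,9.25,93.99,0.60,5.41
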