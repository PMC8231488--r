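condition,method,subject,mean,sd
clean,KF,rat_A,0.5783,0.1074
clean,KF,rat_B,0.5558,0.0653
clean,NN,rat_A,0.2633,0.0787
clean,NN,rat_B,0.4119,0.0588
clean,NMCIF,rat_A,0.2451,0.0684
clean,NMCIF,rat_B,0.3906,0.0491
bad_init,KF,rat_A,2.8686,0.2112
bad_init,KF,rat_B,1.8142,0.1218
bad_init,NMCIF,rat_A,1.8978,0.0661
bad_init,NMCIF,rat_B,1.3425,0.0477
contaminated,NIF,rat_A,0.4113,0.1165
contaminated,NIF,rat_B,0.4962,0.0456
contaminated,NMCIF_A,rat_A,0.2933,0.0630
contaminated,NMCIF_A,rat_B,0.4548,0.0453
contaminated,NMCIF_B,rat_A,0.2898,0.0637
contaminated,NMCIF_B,rat_B,0.4517,0.0437
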