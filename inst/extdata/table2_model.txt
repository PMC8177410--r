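ln(p/(1-p)) = 2.50−4.83((x_1_)^1.46^(x_9_)^2.27^(x_11_^)−1.76^ (x_14_)^3.67^(x_15_)^0.37^(x_23_)^6.03^ (x_24_)^3.15^ (x_26_)^0.06^(x_29_)^3.96^(x_33_)^1.45^))
+0.30(x_1_)−2.16(x_2_)+0.16(x_3_)−0.44(x_4_)+0.64(x_5_)+0.25(x_6_)−0.17(x_7_)+0.55(x_8_)
−0.70(x_9_)−0.31(x_10_)−0.32(x_11_)−1.55(x_12_)−0.07(x_13_)−0.46(x_14_)+0.22(x_15_)
+0.18(x_16_)+0.63(x_17_)+1.25(x_18_)−2.27(x_19_)−0.05(x_20_)+0.06(x_21_)+0.03(x_22_)
+0.63(x_23_)−2.21(x_24_)+0.14(x_25_)+0.73(x_26_)−0.81(x_27_)+1.01(x_28_)−0.83(x_29_)
−1.34(x_30_)+0.60(x_31_)+3.12(x_32_)+23.50(x_33_)+3.03(x_34_)−23.51(x_35_)−0.50(x_36_)
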