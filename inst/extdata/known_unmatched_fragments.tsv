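molecule	calc_mz	note
1Tc	277.1175	printed-calc inconsistent; 277.1188 (as printed for 6Tc) matches the cap-backbone fragment C14H17N2O4
1Tc	294.1443	plain-sum value 294.1454 matches the observed 294.1457; printed calc ~1.1 mDa low (double electron correction)
2Tc	365.2178	plain-sum 365.2189; printed calc ~1.1 mDa low
2To	210.0766	open-cap acylium minus CO; CO is outside the modeled H2O/NH3 loss set
2To	282.1807	plain-sum 282.1818; printed calc ~1.1 mDa low
2To	383.2283	plain-sum 383.2294 matches the observed 383.2294; printed calc ~1.1 mDa low
5	89.1068	protonated putrescine is 89.1079 plain-sum (89.1073 proton convention); printed value matches neither
5Tc	192.0661	closed-cap acylium minus CO; CO loss not modeled
5Tc	225.1228	plain-sum 225.1239 matches the observed 225.1237; printed calc ~1.1 mDa low
5Tc	308.1599	plain-sum 308.1610 (printed correctly in the spermidine analog row); ~1.1 mDa low here
5To	225.1228	plain-sum 225.1239; printed calc ~1.1 mDa low
5To	210.0766	open-cap acylium minus CO; CO loss not modeled
6	443.1925	exceeds the precursor mass of this molecule; no depth-1 assignment (likely belongs to the capped analog)
6Tc	351.2021	plain-sum 351.2032; printed calc ~1.1 mDa low
6Tc	443.1925	no depth-1 + single-loss assignment found
6To	210.0766	open-cap acylium minus CO; CO loss not modeled
6To	369.2127	plain-sum 369.2138; printed calc ~1.1 mDa low
9Tc	287.1385	protonated intermediate side is 287.1396 plain-sum; printed calc ~1.1 mDa low
9Sc	287.1385	protonated intermediate side is 287.1396 plain-sum; printed calc ~1.1 mDa low
9To	345.1439	no depth-1 + single-loss assignment found
9To	389.1934	no depth-1 + single-loss assignment found
10	154.0493	protonated DHB-amide species 154.0504 plain-sum; printed calc ~1.1 mDa low
12	108.0449	aminophenoxy cation from aryl-ether C-O cleavage; ether bonds are not modeled
12	201.1017	protonated oxydianiline is 201.1028 plain-sum; printed calc ~1.1 mDa low
21	145.1694	protonated diaminooctane is 145.1705 plain-sum; printed calc ~1.1 mDa low
Ent dimer	137.02139	printed with five decimals; DHB acylium is 137.0239
Ent dimer	196.0610	unit acylium minus CO; CO loss not modeled
Ent monomer	106.0493	no depth-1 + single-loss assignment found (protonated serine is 106.0504)
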