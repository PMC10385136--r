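source,stratum,ratio,n,N,printed_pct,discrepant
table1,bakery products,labeled_total,2,600,0.3,FALSE
table1,bakery products,labeled_eligible,2,11,18.1,TRUE
table1,bakery products,eligible_total,11,600,1.8,FALSE
table1,bread,labeled_total,4,124,3.2,FALSE
table1,bread,labeled_eligible,4,11,36.4,FALSE
table1,bread,eligible_total,11,124,8.9,FALSE
table1,breakfast cereal,labeled_total,3,141,2.1,FALSE
table1,breakfast cereal,labeled_eligible,3,31,9.7,FALSE
table1,breakfast cereal,eligible_total,31,141,22.0,FALSE
table1,dairy products,labeled_total,89,532,16.7,FALSE
table1,dairy products,labeled_eligible,89,237,37.6,FALSE
table1,dairy products,eligible_total,237,532,44.5,FALSE
table1,fats and oils,labeled_total,3,48,6.3,FALSE
table1,fats and oils,labeled_eligible,3,7,42.9,FALSE
table1,fats and oils,eligible_total,7,48,14.6,FALSE
table1,ice cream,labeled_total,42,317,13.2,FALSE
table1,ice cream,labeled_eligible,42,74,56.8,FALSE
table1,ice cream,eligible_total,74,317,23.3,FALSE
table1,instant foods,labeled_total,64,266,24.1,FALSE
table1,instant foods,labeled_eligible,64,171,37.4,FALSE
table1,instant foods,eligible_total,171,266,64.3,FALSE
table1,instant tea and coffee,labeled_total,132,559,23.6,FALSE
table1,instant tea and coffee,labeled_eligible,132,378,34.9,FALSE
table1,instant tea and coffee,eligible_total,378,559,67.6,FALSE
table1,malted and chocolate drinks,labeled_total,26,149,17.4,FALSE
table1,malted and chocolate drinks,labeled_eligible,26,102,25.5,FALSE
table1,malted and chocolate drinks,eligible_total,102,149,68.5,FALSE
table1,plant-based milk substitutes,labeled_total,125,332,37.7,FALSE
table1,plant-based milk substitutes,labeled_eligible,125,195,64.1,FALSE
table1,plant-based milk substitutes,eligible_total,195,332,57.8,TRUE
table1,prepared meals,labeled_total,12,534,2.2,FALSE
table1,prepared meals,labeled_eligible,12,73,16.4,FALSE
table1,prepared meals,eligible_total,73,534,13.7,FALSE
table1,seasoning,labeled_total,18,322,5.6,FALSE
table1,seasoning,labeled_eligible,18,64,28.1,FALSE
table1,seasoning,eligible_total,64,322,19.9,FALSE
table1,small meals,labeled_total,0,84,0.0,FALSE
table1,small meals,labeled_eligible,0,7,0.0,FALSE
table1,small meals,eligible_total,7,84,8.3,FALSE
table1,snacks (starch- and meat-based),labeled_total,7,2112,0.3,FALSE
table1,snacks (starch- and meat-based),labeled_eligible,7,60,11.7,FALSE
table1,snacks (starch- and meat-based),eligible_total,60,2112,2.8,FALSE
table1,snacks (nut- and bean-based),labeled_total,13,359,3.6,FALSE
table1,snacks (nut- and bean-based),labeled_eligible,13,70,18.6,FALSE
table1,snacks (nut- and bean-based),eligible_total,70,359,19.5,FALSE
table1,soups,labeled_total,5,84,6.0,FALSE
table1,soups,labeled_eligible,5,49,10.2,FALSE
table1,soups,eligible_total,49,84,58.3,FALSE
table1,soft drinks,labeled_total,132,512,25.8,FALSE
table1,soft drinks,labeled_eligible,132,260,50.8,FALSE
table1,soft drinks,eligible_total,260,512,50.8,FALSE
table1,vegetable and fruit juices,labeled_total,152,692,22.0,FALSE
table1,vegetable and fruit juices,labeled_eligible,152,297,51.2,FALSE
table1,vegetable and fruit juices,eligible_total,297,692,42.9,FALSE
table1,Total,labeled_total,829,7767,10.7,FALSE
table1,Total,labeled_eligible,829,2097,39.5,FALSE
table1,Total,eligible_total,2097,7767,27.0,FALSE
table2,MN Beverage,labeled_eligible,26,26,100.0,FALSE
table2,4Care,labeled_eligible,6,6,100.0,FALSE
table2,Green Spot,labeled_eligible,13,13,100.0,FALSE
table2,Sermsuk,labeled_eligible,7,7,100.0,FALSE
table2,Mae-Ruay Snack Food Factory,labeled_eligible,7,7,100.0,FALSE
table2,Perfect Companion Group,labeled_eligible,6,6,100.0,FALSE
table2,The Coca-Cola Company,labeled_eligible,22,23,95.7,FALSE
table2,Dairy Plus,labeled_eligible,14,15,93.3,FALSE
table2,Suntory,labeled_eligible,19,21,90.5,FALSE
table2,CP-Meiji,labeled_eligible,14,16,87.5,FALSE
table2,Taveephol Product,labeled_eligible,7,8,87.5,FALSE
table2,Uni-President Enterprises,labeled_eligible,12,14,85.7,FALSE
table2,Nam-Chao,labeled_eligible,6,7,85.7,FALSE
table2,Tofusan,labeled_eligible,35,41,85.4,FALSE
table2,Asahi Group,labeled_eligible,8,10,80.0,FALSE
table2,Medifoods,labeled_eligible,7,9,77.8,FALSE
table2,Oishi Group,labeled_eligible,16,21,76.2,FALSE
table2,Kewpie,labeled_eligible,6,8,75.0,FALSE
table2,Dutch Mill,labeled_eligible,17,23,73.9,FALSE
table2,Toyo Seikan,labeled_eligible,8,11,72.7,FALSE
table2,Ajinomoto,labeled_eligible,12,17,70.6,FALSE
table2,PepsiCo,labeled_eligible,38,56,67.9,FALSE
table2,Malee Group,labeled_eligible,10,15,66.7,FALSE
table2,Meiji,labeled_eligible,10,15,66.7,FALSE
table2,Unilever,labeled_eligible,37,56,66.1,FALSE
table2,Fraser and Neave,labeled_eligible,7,11,63.6,FALSE
table2,Doi Kham Food Products,labeled_eligible,10,16,62.5,FALSE
table2,Chabaa Bangkok,labeled_eligible,8,13,61.5,FALSE
table2,T.C. Pharmaceutical Industries,labeled_eligible,14,26,53.8,FALSE
table2,Thai President Foods,labeled_eligible,12,25,48.0,FALSE
table2,Nestle,labeled_eligible,49,104,47.1,FALSE
table2,Nissin Foods,labeled_eligible,7,18,38.9,FALSE
table2,Sappe,labeled_eligible,11,32,34.4,FALSE
table2,FrieslandCampina,labeled_eligible,7,24,29.2,FALSE
table2,Tesco,labeled_eligible,10,35,28.6,FALSE
table2,Charoen Pokphand,labeled_eligible,11,40,27.5,FALSE
table2,Ichitan Group,labeled_eligible,7,29,24.1,FALSE
table2,All other companies,labeled_eligible,313,1668,18.8,FALSE
table2,Total,labeled_eligible,829,2097,39.5,FALSE
text,HSR >= 3.5,eligible_total,855,1862,45.9,FALSE
text,HSR 5.0,eligible_total,113,168,67.3,FALSE
text,HSR <= 3.0,eligible_total,1240,5905,21.0,FALSE
text,HSR 0.5,eligible_total,129,1213,10.6,FALSE
text,manufacturers displaying,labeled_total,192,1875,10.2,FALSE
text,overall,labeled_total,829,7767,10.7,FALSE
text,overall,labeled_eligible,829,2097,39.5,FALSE
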