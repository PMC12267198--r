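year,target_population,treated_scenario_ii
2022,978,619
2023,1001,776
2024,1021,877
2025,1042,917
2026,1062,939
2027,1082,959
2028,1103,977
2029,1123,996
2030,1123,996
2031,1123,996
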