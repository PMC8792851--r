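year,entrant_count
2016,20000000
2017,20000000
2018,20000000
2019,20000000
2020,20000000
2021,20000000
2022,20000000
2023,20000000
2024,20000000
2025,20000000
2026,20000000
2027,20000000
2028,20000000
2029,20000000
2030,20000000
2031,20000000
2032,20000000
2033,20000000
2034,20000000
2035,20000000
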