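day,measured,predicted
1,67.83,67.22
2,,67.24
3,,67.25
4,,67.27
5,,67.29
6,,67.31
7,,67.33
8,,67.35
9,,67.37
10,,67.39
11,,67.41
12,,67.43
13,,67.45
14,,67.47
15,,67.49
16,,67.51
17,,67.53
18,,67.55
19,,67.57
20,,67.60
21,67.54,67.62
22,,67.64
23,,67.66
24,,67.69
25,,67.71
26,,67.73
27,,67.76
28,73.21,67.78
29,,67.81
30,,67.83
31,,67.86
32,70.68,67.88
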