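# SWC export (rgcstim)
1 1 0.00000000000 0.000000000000 0 10.00000 -1
2 2 12.50000000000 0.000000000000 0 0.84375 1
3 2 22.50000000000 0.000000000000 0 0.71875 2
4 2 32.50000000000 0.000000000000 0 0.59375 3
5 2 42.50000000000 0.000000000000 0 0.50000 4
6 2 52.50000000000 0.000000000000 0 0.50000 5
7 2 62.50000000000 0.000000000000 0 0.50000 6
8 2 72.50000000000 0.000000000000 0 0.50000 7
9 2 82.50000000000 0.000000000000 0 0.50000 8
10 2 92.50000000000 0.000000000000 0 0.50000 9
11 2 102.50000000000 0.000000000000 0 0.50000 10
12 2 112.50000000000 0.000000000000 0 0.50000 11
13 2 122.50000000000 0.000000000000 0 0.50000 12
14 2 132.50000000000 0.000000000000 0 0.50000 13
15 2 142.50000000000 0.000000000000 0 0.50000 14
16 2 160.00000000000 0.000000000000 0 0.50000 15
17 2 180.00000000000 0.000000000000 0 0.50000 16
18 2 200.00000000000 0.000000000000 0 0.50000 17
19 3 7.23965926157 16.479906971110 -12 1.00000 1
20 3 5.08910441278 38.666536129783 -12 0.60000 19
21 3 -1.80157762186 59.972946551528 -12 0.35000 20
22 3 15.53365038505 57.954341560534 -12 0.35000 20
23 3 25.17796378440 29.783722730235 -12 0.60000 19
24 3 31.61546520347 50.994728746886 -12 0.35000 23
25 3 43.31002692500 41.523987859500 -12 0.35000 23
26 3 -17.99948388725 0.136307712519 -12 1.00000 1
27 3 -36.59552176502 -13.482128420466 -12 0.60000 26
28 3 -52.62332112887 -28.823359855634 -12 0.35000 27
29 3 -58.24982433549 -14.386033674519 -12 0.35000 27
30 3 -37.89167840787 9.231506238671 -12 0.60000 26
31 3 -59.48872987886 7.816074295935 -12 0.35000 30
32 3 -55.32568431234 23.217852083498 -12 0.35000 30
33 3 8.83322933279 -15.683560168350 -12 1.00000 1
34 3 28.83221032369 -26.262209500546 -12 0.60000 33
35 3 49.61101215865 -33.745332604592 -12 0.35000 34
36 3 33.99324090734 -49.441476238234 -12 0.35000 34
37 3 5.43133182854 -38.619951250206 -12 0.60000 33
38 3 19.40411842042 -56.775700685472 -12 0.35000 37
39 3 -1.16873189903 -59.988616134632 -12 0.35000 37
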