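"cell_id","arrival_time_s","departure_time_s"
1,72,73.4
1,72,73.6
1,72,77.2
1,72,78.7
2,34.3,38.5
2,34.3,39.3
2,34.3,39.6
2,34.3,40.3
3,15.9,20.7
3,15.9,20.8
3,15.9,22
3,15.9,24.6
4,0.2,1.1
4,0.2,4.8
4,0.2,5.4
4,0.2,6.5
5,17.9,21.4
5,17.9,21.8
5,17.9,21.8
5,17.9,25.3
6,45.1,46.8
6,45.1,48.8
6,45.1,49.3
6,45.1,51.7
7,8.6,14.7
7,8.6,14.8
7,8.6,15.1
7,8.6,16.1
8,17.7,20.1
8,17.7,20.4
8,17.7,22.4
8,17.7,22.4
9,97,98.8
9,97,99.2
9,97,99.5
9,97,116
10,72.6,78.9
10,72.6,80
10,72.6,81.3
10,72.6,83.8
11,61.7,62.6
11,61.7,63.4
11,61.7,66.9
11,61.7,69.6
12,5.6,7.9
12,5.6,10.2
12,5.6,12.5
12,5.6,12.7
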