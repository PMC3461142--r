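population,level,duration_days,estimate,ci_low,ci_high
1,10,2,2.4,1.2,3.7
1,50,2,13.2,10.0,16.8
1,90,2,73.5,52.6,4119
2,10,2,6.1,4.3,7.9
2,50,2,14.6,12.1,17.3
2,90,2,34.7,28.7,45.2
3,10,2,4.5,2.8,6.2
3,50,2,15.9,12.9,19.3
3,90,2,56.1,43.4,80.5
4,10,2,9.6,6.5,12.1
4,50,2,19.7,16.6,22.5
4,90,2,40.3,34.2,51.8
5,10,2,6.6,4.4,8.6
5,50,2,17.4,14.4,20.5
5,90,2,45.9,37.3,61.3
6,10,2,5.6,3.4,7.9
6,50,2,23.5,19,28.7
6,90,2,98.3,72.9,152
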