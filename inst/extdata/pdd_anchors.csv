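energy_mv,kind,key,value,source
2,depth_at_percent,100,0.5,mc
2,depth_at_percent,90,2.9,mc
2,depth_at_percent,80,4.7,mc
2,depth_at_percent,70,6.9,mc
2,depth_at_percent,60,9,mc
2,depth_at_percent,50,11.2,mc
2,percent_at_depth,0,73.9,mc
2,percent_at_depth,10,55.8,mc
2,percent_at_depth,20,24.9,mc
2,percent_at_depth,30,11.1,mc
3,depth_at_percent,100,0.7,mc
3,depth_at_percent,90,3.1,mc
3,depth_at_percent,80,5.2,mc
3,depth_at_percent,70,7.4,mc
3,depth_at_percent,60,9.6,mc
3,depth_at_percent,50,12.2,mc
3,percent_at_depth,0,60.5,mc
3,percent_at_depth,10,58.7,mc
3,percent_at_depth,20,29.1,mc
3,percent_at_depth,30,14.3,mc
4,depth_at_percent,100,1.1,mc
4,depth_at_percent,90,3.3,mc
4,depth_at_percent,80,5.7,mc
4,depth_at_percent,70,8,mc
4,depth_at_percent,60,10.4,mc
4,depth_at_percent,50,13.2,mc
4,percent_at_depth,0,51.2,mc
4,percent_at_depth,10,61,mc
4,percent_at_depth,20,32.2,mc
4,percent_at_depth,30,16.8,mc
5,depth_at_percent,100,1.3,mc
5,depth_at_percent,90,3.8,mc
5,depth_at_percent,80,6,mc
5,depth_at_percent,70,8.6,mc
5,depth_at_percent,60,11.3,mc
5,depth_at_percent,50,14.3,mc
5,percent_at_depth,0,41.5,mc
5,percent_at_depth,10,64.7,mc
5,percent_at_depth,20,35.9,mc
5,percent_at_depth,30,19.8,mc
6,depth_at_percent,100,1.5,mc
6,depth_at_percent,90,4.2,mc
6,depth_at_percent,80,6.6,mc
6,depth_at_percent,70,9.2,mc
6,depth_at_percent,60,12,mc
6,depth_at_percent,50,15,mc
6,percent_at_depth,0,36.1,mc
6,percent_at_depth,10,66.5,mc
6,percent_at_depth,20,38.5,mc
6,percent_at_depth,30,22,mc
6,depth_at_percent,100,1.6,measured
6,depth_at_percent,90,4.2,measured
6,depth_at_percent,80,6.6,measured
6,depth_at_percent,70,9.2,measured
6,depth_at_percent,60,12,measured
6,depth_at_percent,50,15.2,measured
6,percent_at_depth,0,63.7,measured
6,percent_at_depth,10,66.7,measured
6,percent_at_depth,20,38.2,measured
6,percent_at_depth,30,21.7,measured
10,depth_at_percent,100,2.4,mc
10,depth_at_percent,90,5.6,mc
10,depth_at_percent,80,8.2,mc
10,depth_at_percent,70,11.1,mc
10,depth_at_percent,60,14.5,mc
10,depth_at_percent,50,18.3,mc
10,percent_at_depth,0,23.4,mc
10,percent_at_depth,10,73.9,mc
10,percent_at_depth,20,46.3,mc
10,percent_at_depth,30,29,mc
10,depth_at_percent,100,2.4,measured
10,depth_at_percent,90,5.5,measured
10,depth_at_percent,80,8.2,measured
10,depth_at_percent,70,11.1,measured
10,depth_at_percent,60,14.4,measured
10,depth_at_percent,50,18.3,measured
10,percent_at_depth,0,44.7,measured
10,percent_at_depth,10,73.4,measured
10,percent_at_depth,20,46.3,measured
10,percent_at_depth,30,29,measured
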