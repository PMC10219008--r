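"condition","subject","rate_hz","threshold_db"
"nb2","s1",2,-8.5
"nb2","s1",3.28134142403055,-6.35714285714286
"nb2","s1",5.38360077052942,-11.9285714285714
"nb2","s1",8.8327161093905,-22.6428571428571
"nb2","s1",14.4915786282225,-33.3571428571428
"nb2","s1",23.7759086261912,-42.3571428571429
"nb2","s1",39.0084369345432,-50.9285714285714
"nb2","s1",64,-59.5
"nb2","s2",2,-7
"nb2","s2",3.28134142403055,-4.85714285714286
"nb2","s2",5.38360077052942,-10.4285714285714
"nb2","s2",8.8327161093905,-21.1428571428571
"nb2","s2",14.4915786282225,-31.8571428571428
"nb2","s2",23.7759086261912,-40.8571428571429
"nb2","s2",39.0084369345432,-49.4285714285714
"nb2","s2",64,-58
"nb2","s3",2,-5.5
"nb2","s3",3.28134142403055,-3.35714285714286
"nb2","s3",5.38360077052942,-8.92857142857143
"nb2","s3",8.8327161093905,-19.6428571428571
"nb2","s3",14.4915786282225,-30.3571428571428
"nb2","s3",23.7759086261912,-39.3571428571429
"nb2","s3",39.0084369345432,-47.9285714285714
"nb2","s3",64,-56.5
"nb3","s1",3,-6.74511249783653
"nb3","s1",4.95079975968155,-10.1149239873607
"nb3","s1",8.17013942015431,-20.9554104639041
"nb3","s1",13.4829080926216,-31.7958969404474
"nb3","s1",22.2503927149198,-41.2091067335926
"nb3","s1",36.7190796352817,-49.8814959148273
"nb3","s1",60.5962702113602,-58.553885096062
"nb3","s1",100,-67.2262742772967
"nb3","s2",3,-5.24511249783653
"nb3","s2",4.95079975968155,-8.61492398736071
"nb3","s2",8.17013942015431,-19.4554104639041
"nb3","s2",13.4829080926216,-30.2958969404474
"nb3","s2",22.2503927149198,-39.7091067335926
"nb3","s2",36.7190796352817,-48.3814959148273
"nb3","s2",60.5962702113602,-57.053885096062
"nb3","s2",100,-65.7262742772967
"nb3","s3",3,-3.74511249783653
"nb3","s3",4.95079975968155,-7.11492398736071
"nb3","s3",8.17013942015431,-17.9554104639041
"nb3","s3",13.4829080926216,-28.7958969404474
"nb3","s3",22.2503927149198,-38.2091067335926
"nb3","s3",36.7190796352817,-46.8814959148273
"nb3","s3",60.5962702113602,-55.553885096062
"nb3","s3",100,-64.2262742772967
"nb31","s1",3,-11.5
"nb31","s1",4.95079975968155,-11.5
"nb31","s1",8.17013942015431,-11.2715068383798
"nb31","s1",13.4829080926216,-9.10340954307114
"nb31","s1",22.2503927149198,-6.93531224776247
"nb31","s1",36.7190796352817,-9.16392523773103
"nb31","s1",60.5962702113602,-20.0044117142744
"nb31","s1",100,-30.8448981908178
"nb31","s2",3,-10
"nb31","s2",4.95079975968155,-10
"nb31","s2",8.17013942015431,-9.77150683837981
"nb31","s2",13.4829080926216,-7.60340954307114
"nb31","s2",22.2503927149198,-5.43531224776247
"nb31","s2",36.7190796352817,-7.66392523773103
"nb31","s2",60.5962702113602,-18.5044117142744
"nb31","s2",100,-29.3448981908178
"nb31","s3",3,-8.5
"nb31","s3",4.95079975968155,-8.5
"nb31","s3",8.17013942015431,-8.27150683837981
"nb31","s3",13.4829080926216,-6.10340954307114
"nb31","s3",22.2503927149198,-3.93531224776247
"nb31","s3",36.7190796352817,-6.16392523773103
"nb31","s3",60.5962702113602,-17.0044117142744
"nb31","s3",100,-27.8448981908178
"nb314","s1",3,-11.5
"nb314","s1",6.66328235023962,-11.5
"nb314","s1",14.7997772263383,-11.5
"nb314","s1",32.8716981265794,-11.5
"nb314","s1",73.0111353164139,-11.5
"nb314","s1",162.164603108272,-8.35991683939663
"nb314","s1",360.182845908322,-8.46947370813167
"nb314","s1",800,-25.7385316132465
"nb314","s2",3,-10
"nb314","s2",6.66328235023962,-10
"nb314","s2",14.7997772263383,-10
"nb314","s2",32.8716981265794,-10
"nb314","s2",73.0111353164139,-10
"nb314","s2",162.164603108272,-6.85991683939663
"nb314","s2",360.182845908322,-6.96947370813167
"nb314","s2",800,-24.2385316132465
"nb314","s3",3,-8.5
"nb314","s3",6.66328235023962,-8.5
"nb314","s3",14.7997772263383,-8.5
"nb314","s3",32.8716981265794,-8.5
"nb314","s3",73.0111353164139,-8.5
"nb314","s3",162.164603108272,-5.35991683939663
"nb314","s3",360.182845908322,-5.46947370813167
"nb314","s3",800,-22.7385316132465
"bb_short","s1",4,-23.5
"bb_short","s1",7.24578931411125,-23.5
"bb_short","s1",13.1253656961222,-23.5
"bb_short","s1",23.7759086261912,-21.2142857142857
"bb_short","s1",43.0688061642354,-17.7857142857143
"bb_short","s1",78.0168738690864,-14.3571428571429
"bb_short","s1",141.323457750248,-10.9285714285714
"bb_short","s1",256,-7.5
"bb_short","s2",4,-22
"bb_short","s2",7.24578931411125,-22
"bb_short","s2",13.1253656961222,-22
"bb_short","s2",23.7759086261912,-19.7142857142857
"bb_short","s2",43.0688061642354,-16.2857142857143
"bb_short","s2",78.0168738690864,-12.8571428571429
"bb_short","s2",141.323457750248,-9.42857142857143
"bb_short","s2",256,-6
"bb_short","s3",4,-20.5
"bb_short","s3",7.24578931411125,-20.5
"bb_short","s3",13.1253656961222,-20.5
"bb_short","s3",23.7759086261912,-18.2142857142857
"bb_short","s3",43.0688061642354,-14.7857142857143
"bb_short","s3",78.0168738690864,-11.3571428571429
"bb_short","s3",141.323457750248,-7.92857142857143
"bb_short","s3",256,-4.5
"bb_long","s1",2,-23.5
"bb_long","s1",4.8760546168179,-23.5
"bb_long","s1",11.8879543130956,-23.5
"bb_long","s1",28.983157256445,-20.0714285714286
"bb_long","s1",70.661728875124,-14.9285714285714
"bb_long","s1",172.275224656942,-9.78571428571428
"bb_long","s1",420.011702275911,-4.64285714285714
"bb_long","s1",1024,-1.5
"bb_long","s2",2,-22
"bb_long","s2",4.8760546168179,-22
"bb_long","s2",11.8879543130956,-22
"bb_long","s2",28.983157256445,-18.5714285714286
"bb_long","s2",70.661728875124,-13.4285714285714
"bb_long","s2",172.275224656942,-8.28571428571428
"bb_long","s2",420.011702275911,-3.14285714285714
"bb_long","s2",1024,0
"bb_long","s3",2,-20.5
"bb_long","s3",4.8760546168179,-20.5
"bb_long","s3",11.8879543130956,-20.5
"bb_long","s3",28.983157256445,-17.0714285714286
"bb_long","s3",70.661728875124,-11.9285714285714
"bb_long","s3",172.275224656942,-6.78571428571428
"bb_long","s3",420.011702275911,-1.64285714285714
"bb_long","s3",1024,0
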