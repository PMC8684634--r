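creatinine,age,female,black,egfr_expected
0.4,25,0,0,262.10722769814203
0.4,40,1,0,176.7854611497674
0.4,55,0,1,270.68850440850589
0.4,70,1,1,191.25484317993095
0.4,85,0,0,204.45078235561264
0.5,25,1,0,150.33106950959413
0.5,40,0,1,223.20869341747438
0.5,55,1,1,155.25284338418735
0.5,70,0,0,164.3886244941706
0.5,85,1,0,117.26233207498221
0.6,25,0,1,198.96299227210889
0.6,40,1,1,134.19608703454197
0.6,55,0,0,139.88072667178734
0.6,70,1,0,98.83266562045704
0.6,85,0,1,155.1965574817864
0.7,25,1,1,123.57186857749153
0.7,40,0,0,124.90411089037787
0.7,55,1,0,86.877074854051725
0.7,70,0,1,135.12715347463038
0.7,85,1,1,96.389425921932243
0.8,25,0,0,117.78510730775482
0.8,40,1,0,79.443419759324241
0.8,55,0,1,121.6413405259085
0.8,70,1,1,85.945635398575743
0.8,85,0,0,91.875594390871364
0.9,25,1,0,76.289413532606654
0.9,40,0,1,113.27306039761636
0.9,55,1,1,78.787095772596693
0.9,70,0,0,83.423285652150558
0.9,85,1,0,59.507822119866161
1.0,25,0,1,110.34657218714835
1.0,40,1,1,74.426294237361849
1.0,55,0,0,77.579043856403213
1.0,70,1,0,54.813439156669062
1.0,85,0,1,86.073334230616822
1.1,25,1,1,73.349235786794776
1.1,40,0,0,74.140022206535334
1.1,55,1,0,51.5681046284476
1.1,70,0,1,80.208169994561628
1.1,85,1,1,57.214403332162653
1.2,25,0,0,73.770218362388022
1.2,40,1,0,49.756361878479595
1.2,55,0,1,76.18542324746912
1.2,70,1,1,53.828777131229778
1.2,85,0,0,57.542781216641456
1.3,25,1,0,49.907923836270476
1.3,40,0,1,74.102329658220193
1.3,55,1,1,51.541887570273362
1.3,70,0,0,54.574845888931397
1.3,85,1,0,38.929541026701558
1.4,25,0,1,74.838847970973669
1.4,40,1,1,50.477128641804712
1.4,55,0,0,52.615374939386231
1.4,70,1,0,37.175369914118057
1.4,85,0,1,58.376341440991029
1.5,25,1,1,51.280640282918365
1.5,40,0,0,51.833502674684867
1.5,55,1,0,36.052801302660665
1.5,70,0,1,56.075925933270272
1.5,85,1,1,40.000297273808158
1.7,25,0,0,49.353524400330217
1.7,40,1,0,33.287848057844773
1.7,55,0,1,50.969337337769218
1.7,70,1,1,36.01236277403487
1.7,85,0,0,38.497094354357087
1.9,25,1,0,32.209091615903743
1.9,40,0,1,47.823442480669497
1.9,55,1,1,33.263603275779995
1.9,70,0,0,35.220984485893145
1.9,85,1,0,25.123969444364176
2.2,25,0,1,44.422507881659713
2.2,40,1,1,29.961987734014928
2.2,55,0,0,31.231198385735345
2.2,70,1,0,22.066389419222902
2.2,85,0,1,34.650767055776528
2.5,25,1,1,28.44068040072134
2.5,40,0,0,28.747302597773881
2.5,55,1,0,19.995191045639743
2.5,70,0,1,31.100186714593409
2.5,85,1,1,22.184505973829866
3.0,25,0,0,25.624671051262403
3.0,40,1,0,17.283267342118512
3.0,55,0,1,26.463611643759813
3.0,70,1,1,18.697853113347196
3.0,85,0,0,19.987941919973824
3.5,25,1,0,15.914962110930894
3.5,40,0,1,23.630230997211014
3.5,55,1,1,16.436011053030793
3.5,70,0,0,17.403180452499893
3.5,85,1,0,12.414104270665325
4.2,25,0,1,21.063433485956566
4.2,40,1,1,14.206814649540014
4.2,55,0,0,14.808625204977339
4.2,70,1,0,10.463027595047426
4.2,85,0,1,16.430052284780073
5.0,25,1,1,12.78060365722707
5.0,40,0,0,12.918392792993925
5.0,55,1,0,8.9853902299178377
5.0,70,0,1,13.975726124150533
5.0,85,1,1,9.9692192376563035
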