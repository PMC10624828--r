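hc,fl,ga_days
130.0,20.0,60.928741437667473
130.0,35.0,68.699258627548526
130.0,50.0,77.460784920416042
130.0,65.0,87.339708176717834
130.0,80.0,98.478535070765727
142.0,20.0,62.849035410594285
142.0,35.0,71.018917319673966
142.0,50.0,80.250819830537713
142.0,65.0,90.682797295888019
142.0,80.0,102.47085005202514
154.0,20.0,64.695588388132622
154.0,35.0,73.251905755802598
154.0,50.0,82.939839184479297
154.0,65.0,93.909050596985606
154.0,80.0,106.32899545912676
166.0,20.0,66.477032459767284
166.0,35.0,75.408358953509381
166.0,50.0,85.539627592474288
166.0,65.0,97.032053080087166
166.0,80.0,110.06850964786287
178.0,20.0,68.20044612482766
178.0,35.0,77.49658637367981
178.0,50.0,88.059847710979932
178.0,65.0,100.06294653405086
178.0,80.0,113.70214154739993
190.0,20.0,69.871718338569652
190.0,35.0,79.523500300951856
190.0,50.0,90.508538368443232
190.0,65.0,103.01100286821642
190.0,80.0,117.240504633046
202.0,20.0,71.495809941115074
202.0,35.0,81.494923273058827
202.0,50.0,92.89247194698139
202.0,65.0,105.88403544486021
202.0,80.0,120.69254619994789
214.0,20.0,73.076945704280271
214.0,35.0,83.415813800152763
214.0,50.0,95.217416722634041
214.0,65.0,108.68870103039317
214.0,80.0,124.06589191645311
226.0,20.0,74.618758225444749
226.0,35.0,85.290435414709956
226.0,50.0,97.488333312282918
226.0,65.0,111.43072591663227
226.0,80.0,127.36710390291576
238.0,20.0,76.124397630587011
238.0,35.0,87.122485507033514
238.0,50.0,99.709524372951469
238.0,65.0,114.11507824667804
238.0,80.0,130.60187745492888
250.0,20.0,77.596616507079179
250.0,35.0,88.915195041006115
250.0,50.0,101.88475045762979
250.0,65.0,116.74610139499991
250.0,80.0,133.77519334063328
262.0,20.0,79.03783656779917
262.0,35.0,90.671406802293943
262.0,50.0,104.01732092521014
262.0,65.0,119.32761864001904
262.0,80.0,136.89143734566968
274.0,20.0,80.450201624723092
274.0,35.0,92.393637564554147
274.0,50.0,106.11016616503817
274.0,65.0,121.86301633275612
274.0,80.0,139.95449528012001
286.0,20.0,81.835620154396909
286.0,35.0,94.08412803314909
286.0,50.0,108.16589562170496
286.0,65.0,124.35531072279594
286.0,80.0,142.96782933362978
298.0,20.0,83.195799847203311
298.0,35.0,95.744883377704958
298.0,50.0,110.18684488695954
298.0,65.0,126.80720220053088
298.0,80.0,145.93454006621963
310.0,20.0,84.532275909280378
310.0,35.0,97.377706431818235
310.0,50.0,112.175114273486
310.0,65.0,129.22111973421932
310.0,80.0,148.85741720445255
322.0,20.0,85.846434442834342
322.0,35.0,98.984225117107724
322.0,50.0,114.13260067963248
322.0,65.0,131.59925758357106
322.0,80.0,151.73898161805081
334.0,20.0,87.139531910728637
334.0,35.0,100.56591527279328
334.0,50.0,116.06102411722342
334.0,65.0,133.94360586884534
334.0,80.0,154.58152027874581
346.0,20.0,88.412711457176634
346.0,35.0,102.12411979692722
346.0,50.0,117.96194995499794
346.0,65.0,136.25597620675035
346.0,80.0,157.38711558377309
358.0,20.0,89.667016682941004
358.0,35.0,103.66006480166099
358.0,50.0,119.83680769351224
358.0,65.0,138.53802335209157
358.0,80.0,160.15767011577139
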