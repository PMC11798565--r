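age_group,gender,region,proportion
20-29,male,Hokkaido,0.0032144
20-29,male,Tohoku,0.0053312
20-29,male,North Kanto,0.0041551999999999995
20-29,male,Greater Tokyo,0.022736
20-29,male,Koshinetsu,0.0032144
20-29,male,Hokuriku,0.0018031999999999998
20-29,male,Tokai,0.009016
20-29,male,Kinki ex Keihanshin,0.0036063999999999996
20-29,male,Keihanshin,0.010192
20-29,male,Chugoku,0.0044688
20-29,male,Shikoku,0.0022736
20-29,male,Kyushu ex Okinawa,0.007448
20-29,male,Okinawa,9.408e-4
20-29,female,Hokkaido,0.0033456000000000002
20-29,female,Tohoku,0.0055488000000000004
20-29,female,North Kanto,0.0043248
20-29,female,Greater Tokyo,0.023664
20-29,female,Koshinetsu,0.0033456000000000002
20-29,female,Hokuriku,0.0018768
20-29,female,Tokai,0.009384000000000002
20-29,female,Kinki ex Keihanshin,0.0037536
20-29,female,Keihanshin,0.010608000000000001
20-29,female,Chugoku,0.0046512
20-29,female,Shikoku,0.0023664000000000003
20-29,female,Kyushu ex Okinawa,0.007752000000000001
20-29,female,Okinawa,9.792000000000002e-4
30-39,male,Hokkaido,0.0036162
30-39,male,Tohoku,0.0059976000000000005
30-39,male,North Kanto,0.0046746
30-39,male,Greater Tokyo,0.025578
30-39,male,Koshinetsu,0.0036162
30-39,male,Hokuriku,0.0020286
30-39,male,Tokai,0.010143000000000001
30-39,male,Kinki ex Keihanshin,0.0040572
30-39,male,Keihanshin,0.011466
30-39,male,Chugoku,0.0050274000000000004
30-39,male,Shikoku,0.0025578000000000003
30-39,male,Kyushu ex Okinawa,0.008379
30-39,male,Okinawa,0.0010584
30-39,female,Hokkaido,0.0037638
30-39,female,Tohoku,0.0062424
30-39,female,North Kanto,0.0048654
30-39,female,Greater Tokyo,0.026621999999999996
30-39,female,Koshinetsu,0.0037638
30-39,female,Hokuriku,0.0021114
30-39,female,Tokai,0.010557
30-39,female,Kinki ex Keihanshin,0.0042228
30-39,female,Keihanshin,0.011934
30-39,female,Chugoku,0.0052326
30-39,female,Shikoku,0.0026622
30-39,female,Kyushu ex Okinawa,0.008721
30-39,female,Okinawa,0.0011015999999999999
40-49,male,Hokkaido,0.0042189
40-49,male,Tohoku,0.0069972
40-49,male,North Kanto,0.0054537
40-49,male,Greater Tokyo,0.029840999999999996
40-49,male,Koshinetsu,0.0042189
40-49,male,Hokuriku,0.0023667
40-49,male,Tokai,0.0118335
40-49,male,Kinki ex Keihanshin,0.0047334
40-49,male,Keihanshin,0.013377
40-49,male,Chugoku,0.0058652999999999995
40-49,male,Shikoku,0.0029841
40-49,male,Kyushu ex Okinawa,0.0097755
40-49,male,Okinawa,0.0012347999999999999
40-49,female,Hokkaido,0.0043911
40-49,female,Tohoku,0.007282800000000001
40-49,female,North Kanto,0.0056763
40-49,female,Greater Tokyo,0.031059
40-49,female,Koshinetsu,0.0043911
40-49,female,Hokuriku,0.0024633
40-49,female,Tokai,0.012316500000000001
40-49,female,Kinki ex Keihanshin,0.0049266
40-49,female,Keihanshin,0.013923000000000001
40-49,female,Chugoku,0.0061047
40-49,female,Shikoku,0.0031059
40-49,female,Kyushu ex Okinawa,0.0101745
40-49,female,Okinawa,0.0012852
50-59,male,Hokkaido,0.004018000000000001
50-59,male,Tohoku,0.006664000000000001
50-59,male,North Kanto,0.005194
50-59,male,Greater Tokyo,0.02842
50-59,male,Koshinetsu,0.004018000000000001
50-59,male,Hokuriku,0.002254
50-59,male,Tokai,0.01127
50-59,male,Kinki ex Keihanshin,0.004508
50-59,male,Keihanshin,0.012740000000000001
50-59,male,Chugoku,0.005586000000000001
50-59,male,Shikoku,0.0028420000000000003
50-59,male,Kyushu ex Okinawa,0.00931
50-59,male,Okinawa,0.001176
50-59,female,Hokkaido,0.004182000000000001
50-59,female,Tohoku,0.006936000000000001
50-59,female,North Kanto,0.005406
50-59,female,Greater Tokyo,0.02958
50-59,female,Koshinetsu,0.004182000000000001
50-59,female,Hokuriku,0.002346
50-59,female,Tokai,0.01173
50-59,female,Kinki ex Keihanshin,0.004692
50-59,female,Keihanshin,0.013260000000000001
50-59,female,Chugoku,0.005814000000000001
50-59,female,Shikoku,0.0029580000000000006
50-59,female,Kyushu ex Okinawa,0.00969
50-59,female,Okinawa,0.001224
60-75,male,Hokkaido,0.0050225
60-75,male,Tohoku,0.00833
60-75,male,North Kanto,0.0064925
60-75,male,Greater Tokyo,0.035524999999999994
60-75,male,Koshinetsu,0.0050225
60-75,male,Hokuriku,0.0028174999999999997
60-75,male,Tokai,0.014087500000000001
60-75,male,Kinki ex Keihanshin,0.005634999999999999
60-75,male,Keihanshin,0.015925
60-75,male,Chugoku,0.0069825
60-75,male,Shikoku,0.0035525
60-75,male,Kyushu ex Okinawa,0.0116375
60-75,male,Okinawa,0.00147
60-75,female,Hokkaido,0.0052275
60-75,female,Tohoku,0.00867
60-75,female,North Kanto,0.0067575
60-75,female,Greater Tokyo,0.036975
60-75,female,Koshinetsu,0.0052275
60-75,female,Hokuriku,0.0029325
60-75,female,Tokai,0.0146625
60-75,female,Kinki ex Keihanshin,0.005865
60-75,female,Keihanshin,0.016575
60-75,female,Chugoku,0.0072675000000000005
60-75,female,Shikoku,0.0036975000000000003
60-75,female,Kyushu ex Okinawa,0.0121125
60-75,female,Okinawa,0.0015300000000000001
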