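prefecture,population,environment,latitude,longitude,females,males,total,young_adults
Aomori,Shimokita,wild,41.51,140.93,4,4,8,0
Miyagi,Kinkazan,wild,38.29,141.57,5,2,7,0
Toyama,Hakusan,wild,36.29,136.64,9,9,18,0
Saitama,Nagatoro,captive,36.11,139.11,1,1,2,0
Nagano,Kamimatsu,wild,35.78,137.69,1,0,1,0
Nagano,Matsukawa,wild,35.6,137.91,0,1,1,0
Nagano,Takamori,wild,35.55,137.88,1,0,1,0
Fukui,Takahama,captive,35.49,135.55,19,13,32,10
Fukui,WakasaF,wild,35.49,135.75,6,6,12,3
Aichi,Inuyama,captive,35.38,136.94,1,0,1,0
Shimane,WakasaS,captive,35.34,134.4,12,9,21,0
Shimane,Mitoya,wild,35.3,132.89,1,0,1,0
Shimane,Kotsugu,wild,35.29,132.9,1,1,2,1
Shimane,Yoshida,wild,35.17,132.85,0,1,1,0
Kyoto,Arashiyama,captive,35.01,135.67,9,4,13,2
Shiga,Koga,wild,34.97,136.17,10,5,15,1
Shimane,Hasumi,wild,34.87,132.62,4,4,8,2
Shizuoka,Izu,captive,34.86,138.94,4,1,5,1
Osaka,Minoo,captive,34.85,135.47,1,1,2,0
Kagawa,Shodoshima,captive,34.51,134.3,1,0,1,0
Hiroshima,Miyajima,captive,34.28,132.31,4,5,9,0
Wakayama,Noguchi,wild,33.9,135.18,0,1,1,0
Kagoshima,Yakushima,mixed,30.29,130.44,7,8,15,5
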