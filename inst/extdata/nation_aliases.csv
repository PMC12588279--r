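alias,canonical
China,The Mainland of China
"China, mainland",The Mainland of China
Mainland China,The Mainland of China
Taiwan,Taiwan Province of China
"Taiwan, Province of China",Taiwan Province of China
Chinese Taipei,Taiwan Province of China
Viet Nam,Vietnam
Republic of Korea,South Korea
Korea,South Korea
United States of America,United States
USA,United States
Cote d'Ivoire,Cote D’Ivoire
Ivory Coast,Cote D’Ivoire
Solomon Islands,Solomon Is
Trinidad and Tobago,Trinidad & Tobago
United Republic of Tanzania,Tanzania
Iran (Islamic Republic of),Iran
Venezuela (Bolivarian Republic of),Venezuela
Bolivarian Republic of Venezuela,Venezuela
Democratic Republic of Congo,Democratic Republic of the Congo
DR Congo,Democratic Republic of the Congo
Republic of the Congo,Congo
Macao,Macau
Türkiye,Turkey
Hong Kong SAR,Hong Kong
"Hong Kong, SAR",Hong Kong
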