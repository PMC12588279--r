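nation,mean_annual_kg,range_state_count,fao_rfmo_catch,seizure_implicated,cites_reporting,bolded_in_print
Spain,725105.67,5,TRUE,FALSE,FALSE,TRUE
Singapore,605283,2,FALSE,FALSE,TRUE,FALSE
Senegal,315602.67,4,FALSE,TRUE,TRUE,FALSE
Indonesia,298621.33,3,FALSE,TRUE,TRUE,FALSE
Taiwan Province of China,257287,4,FALSE,FALSE,FALSE,TRUE
Peru,231270.89,4,TRUE,TRUE,TRUE,FALSE
Mexico,144508.44,4,FALSE,TRUE,TRUE,FALSE
Yemen,137076.33,4,FALSE,TRUE,TRUE,FALSE
United Arab Emirates,97553.11,3,FALSE,TRUE,FALSE,TRUE
Argentina,85395.63,3,FALSE,FALSE,FALSE,FALSE
United States,83371.67,5,TRUE,FALSE,TRUE,FALSE
Oman,71103.56,4,TRUE,FALSE,TRUE,FALSE
South Africa,68709,5,FALSE,FALSE,FALSE,FALSE
Ecuador,66424.86,4,TRUE,TRUE,FALSE,TRUE
Sri Lanka,60168.11,4,TRUE,TRUE,TRUE,FALSE
The Mainland of China,55632,4,TRUE,TRUE,FALSE,TRUE
Japan,50087.56,4,TRUE,FALSE,FALSE,FALSE
Costa Rica,48511.67,4,FALSE,TRUE,TRUE,FALSE
Uruguay,35227.57,5,FALSE,FALSE,FALSE,FALSE
India,34888.75,4,FALSE,TRUE,TRUE,FALSE
Philippines,30270.63,4,FALSE,TRUE,FALSE,TRUE
South Korea,28031.13,3,FALSE,FALSE,TRUE,FALSE
Ghana,27104.22,4,FALSE,TRUE,FALSE,TRUE
Brazil,26552.22,5,FALSE,TRUE,FALSE,TRUE
Trinidad & Tobago,24328.5,4,FALSE,FALSE,FALSE,FALSE
New Zealand,23827.5,3,TRUE,FALSE,FALSE,TRUE
France,22245.13,5,FALSE,FALSE,FALSE,FALSE
Togo,19843.75,3,FALSE,FALSE,FALSE,FALSE
Pakistan,15342.11,4,FALSE,TRUE,FALSE,TRUE
Morocco,14602.78,5,TRUE,TRUE,FALSE,TRUE
El Salvador,14326.88,3,FALSE,FALSE,TRUE,FALSE
Guinea,12381.38,4,TRUE,TRUE,FALSE,TRUE
Somalia,12343.38,4,FALSE,TRUE,FALSE,TRUE
Chile,12190.78,3,FALSE,FALSE,FALSE,FALSE
Bangladesh,11658,3,FALSE,FALSE,FALSE,FALSE
Namibia,10725.33,3,FALSE,FALSE,FALSE,FALSE
Guyana,10206.38,3,FALSE,TRUE,FALSE,TRUE
Guatemala,9935.33,3,FALSE,TRUE,FALSE,TRUE
Australia,9710.22,5,FALSE,FALSE,TRUE,FALSE
Malaysia,9642.78,2,FALSE,FALSE,FALSE,FALSE
Madagascar,8633.11,4,FALSE,TRUE,FALSE,TRUE
Kenya,8360.89,3,TRUE,TRUE,TRUE,FALSE
Thailand,8081.67,3,FALSE,FALSE,FALSE,FALSE
Panama,7663.38,4,FALSE,TRUE,FALSE,TRUE
Mauritania,6803,4,TRUE,FALSE,FALSE,TRUE
Mozambique,6719,3,FALSE,FALSE,FALSE,FALSE
Papua New Guinea,6587.78,3,FALSE,FALSE,TRUE,FALSE
Tunisia,5025.13,4,FALSE,FALSE,FALSE,FALSE
Sierra Leone,4829.11,3,FALSE,FALSE,FALSE,FALSE
Colombia,4629.17,4,FALSE,TRUE,TRUE,FALSE
Canada,3531.67,2,FALSE,FALSE,FALSE,FALSE
Nicaragua,3481.11,3,FALSE,TRUE,FALSE,TRUE
Angola,3429.17,3,FALSE,FALSE,FALSE,FALSE
Mauritius,3347.8,3,FALSE,FALSE,FALSE,FALSE
Venezuela,3287.5,3,TRUE,TRUE,FALSE,TRUE
Saudi Arabia,3233.38,4,FALSE,FALSE,FALSE,FALSE
Congo,2842.33,3,FALSE,TRUE,FALSE,TRUE
Vietnam,2652,4,FALSE,FALSE,FALSE,FALSE
Solomon Is,2462.5,3,FALSE,FALSE,FALSE,FALSE
Seychelles,2256.22,4,TRUE,TRUE,FALSE,TRUE
Germany,2131.75,2,FALSE,FALSE,FALSE,FALSE
Democratic Republic of the Congo,2107.25,3,FALSE,TRUE,FALSE,TRUE
Egypt,2002.38,5,FALSE,TRUE,FALSE,TRUE
Cuba,1607.83,4,FALSE,FALSE,FALSE,FALSE
Norway,1357.33,2,FALSE,FALSE,FALSE,FALSE
Turkey,1307.86,0,FALSE,FALSE,FALSE,FALSE
Fiji,1307,3,TRUE,FALSE,FALSE,TRUE
Iran,1106,3,TRUE,FALSE,FALSE,TRUE
Cote D’Ivoire,974,4,FALSE,FALSE,FALSE,FALSE
Nigeria,880.43,2,FALSE,FALSE,FALSE,FALSE
Ethiopia,865.83,0,FALSE,FALSE,FALSE,FALSE
Bahrain,851.89,3,FALSE,FALSE,FALSE,FALSE
Liberia,524.83,4,TRUE,FALSE,FALSE,TRUE
Tanzania,441.71,3,FALSE,TRUE,FALSE,TRUE
Aruba,384,3,FALSE,FALSE,FALSE,FALSE
Belize,307.4,3,FALSE,FALSE,FALSE,FALSE
Mali,293,0,FALSE,FALSE,FALSE,FALSE
Macau,226.2,4,FALSE,FALSE,FALSE,FALSE
Sweden,202,2,FALSE,FALSE,FALSE,FALSE
Maldives,189.43,3,FALSE,FALSE,FALSE,FALSE
Uganda,137.4,0,FALSE,FALSE,FALSE,FALSE
Libya,114,4,FALSE,FALSE,FALSE,FALSE
Zimbabwe,90,0,FALSE,FALSE,FALSE,FALSE
Zambia,83.33,0,FALSE,FALSE,FALSE,FALSE
Kuwait,60.2,3,FALSE,FALSE,FALSE,FALSE
Cameroon,59.75,4,FALSE,FALSE,FALSE,FALSE
Vanuatu,58,1,FALSE,FALSE,FALSE,FALSE
Northern Mariana Islands,46.5,1,FALSE,FALSE,FALSE,FALSE
Sudan,38.6,3,FALSE,FALSE,FALSE,FALSE
Dominican Republic,29.4,4,FALSE,FALSE,FALSE,FALSE
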