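country,survey_year,n_children,u5m_per_1000,maternal_schooling_years
Afghanistan,2015-2016,66306,57,1.0
Albania,2017-2018,5811,6,12.0
Angola,2015-2016,25598,67,4.2
Armenia,2015-2016,3515,10,11.9
Bangladesh,2014,16792,51,5.3
Benin,2017-2018,25343,88,1.8
Burkina Faso,2010,29644,125,0.8
Burundi,2016-2017,25495,71,2.7
Cambodia,2014,14616,44,4.5
Cameroon,2011,22195,110,4.7
Chad,2014-2015,37925,127,1.6
Colombia,2015,24407,17,9.4
Comoros,2012,6091,47,3.7
"Congo, Dem. Rep.",2013-2014,34290,95,5.1
"Congo, Rep.",2011-2012,17221,66,7.1
Côte d'Ivoire,2011-2012,14903,102,2.0
Dominican Republic,2013,7184,33,9.8
"Egypt, Arab Rep.",2014,29661,29,8.3
Ethiopia,2016,21606,73,1.5
Gabon,2012,11182,56,7.5
"Gambia, The",2013,14983,52,2.9
Ghana,2014,11430,61,5.6
Guatemala,2014-2015,24263,36,4.6
Guinea,2012,14081,115,1.2
Haiti,2016-2017,13144,74,5.3
Honduras,2011-2012,21070,31,4.5
India,2015-2016,536386,49,5.7
Indonesia,2012,36714,39,8.8
Jordan,2012,20346,20,11.1
Kenya,2014,42847,50,7.4
Kyrgyz Republic,2012,7685,30,12.1
Lesotho,2014,6026,84,7.6
Liberia,2013,15515,97,3.4
Malawi,2015-2016,34598,65,5.2
Maldives,2016-2017,6319,19,9.6
Mali,2012-2013,19863,91,1.0
Mozambique,2011,20640,93,2.8
Namibia,2013,9433,52,8.3
Nepal,2016,10402,43,4.0
Niger,2012,25117,124,0.7
Nigeria,2013,61629,121,4.4
Pakistan,2017-2018,25677,73,3.9
Peru,2012,19600,22,8.7
Philippines,2017,22158,26,10.2
Rwanda,2014-2015,15876,55,4.2
Senegal,2017,23895,52,2.2
Sierra Leone,2013,24348,156,1.8
South Africa,2016,6994,48,10.4
Tajikistan,2017,11190,30,10.0
Tanzania,2015-2016,19260,67,5.3
Timor-Leste,2016,14387,37,6.7
Togo,2013-2014,13931,81,3.1
Uganda,2016,30086,64,5.7
Zambia,2013-2014,26180,69,5.8
Zimbabwe,2015,11314,74,8.9
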