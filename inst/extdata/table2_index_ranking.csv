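country,survey_year,national_index,units_label,n_units,within_mean,within_sd
Albania,2017-2018,0.755,Counties,12,0.603,0.089
Jordan,2012,0.739,Regions,3,0.625,0.021
Maldives,2016-2017,0.715,Provinces,6,0.572,0.111
Dominican Republic,2013,0.700,"Regions, capital",9,0.520,0.061
Colombia,2015,0.682,Regions,6,0.596,0.099
Armenia,2015-2016,0.681,Divisions,11,0.619,0.083
Philippines,2017,0.665,Regions,17,0.553,0.102
Kyrgyz Republic,2012,0.663,"Regions, capital",9,0.646,0.111
South Africa,2016,0.655,Provinces,9,0.640,0.070
"Egypt, Arab Rep.",2014,0.651,Regions,6,0.621,0.135
Indonesia,2012,0.644,Provinces,33,0.557,0.106
Peru,2012,0.603,"Regions, capital",25,0.554,0.132
Tajikistan,2017,0.589,"Regions, capital",5,0.622,0.109
Gabon,2012,0.561,"Provinces, cities",10,0.481,0.104
Namibia,2013,0.516,Regions,13,0.539,0.097
Honduras,2011-2012,0.515,Departments,18,0.466,0.101
Timor-Leste,2016,0.500,Municipalities,13,0.491,0.092
Zimbabwe,2015,0.496,"Provinces, cities",10,0.566,0.107
Ghana,2014,0.481,Regions,10,0.451,0.172
Guatemala,2014-2015,0.467,Regions,8,0.457,0.110
India,2015-2016,0.467,"States, union territories",36,0.557,0.119
Cambodia,2014,0.449,"Regions, capital",19,0.444,0.092
"Congo, Rep.",2011-2012,0.448,Departments,12,0.425,0.129
Lesotho,2014,0.441,Districts,10,0.534,0.091
Angola,2015-2016,0.437,Provinces,18,0.374,0.086
Pakistan,2017-2018,0.428,"States, territories, capital",6,0.419,0.189
Kenya,2014,0.415,Provinces,8,0.520,0.168
Nepal,2016,0.394,Provinces,7,0.520,0.116
Comoros,2012,0.390,Islands,3,0.399,0.099
Nigeria,2013,0.378,Zones,6,0.498,0.180
Haiti,2016-2017,0.373,"Departments, capital",11,0.486,0.080
Zambia,2013-2014,0.368,Provinces,10,0.471,0.110
Togo,2013-2014,0.367,"Regions, capital",6,0.398,0.139
"Gambia, The",2013,0.365,Local government areas,8,0.370,0.153
Senegal,2017,0.355,Regions,14,0.302,0.112
Bangladesh,2014,0.354,Divisions,7,0.501,0.045
Cameroon,2011,0.347,"Regions, capital",12,0.529,0.169
Tanzania,2015-2016,0.335,Regions,30,0.524,0.097
Uganda,2016,0.326,Regions,15,0.464,0.137
Côte d'Ivoire,2011-2012,0.316,Districts,11,0.321,0.097
Liberia,2013,0.308,"Regions, subregions",5,0.372,0.107
Benin,2017-2018,0.288,Departments,12,0.371,0.116
"Congo, Dem. Rep.",2013-2014,0.271,Provinces,11,0.498,0.102
Malawi,2015-2016,0.268,Regions,3,0.501,0.057
Rwanda,2014-2015,0.267,Provinces,5,0.468,0.096
Afghanistan,2015-2016,0.262,Provinces,34,0.260,0.091
Mozambique,2011,0.260,"Provinces, capital",11,0.435,0.131
Guinea,2012,0.222,Regions,8,0.280,0.126
Sierra Leone,2013,0.205,Provinces,4,0.364,0.139
Mali,2012-2013,0.193,"Regions, capital",6,0.295,0.132
Burundi,2016-2017,0.191,Provinces,18,0.411,0.096
Burkina Faso,2010,0.174,Regions,13,0.251,0.101
Ethiopia,2016,0.159,"Regions, chartered cities",11,0.345,0.152
Chad,2014-2015,0.158,Regions,21,0.269,0.109
Niger,2012,0.140,"Regions, capital",8,0.277,0.114
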