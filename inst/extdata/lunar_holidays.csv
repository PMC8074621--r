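date,group,name
2012-08-19,muslim,Eid al-Fitr
2013-08-08,muslim,Eid al-Fitr
2014-07-28,muslim,Eid al-Fitr
2015-07-17,muslim,Eid al-Fitr
2016-07-06,muslim,Eid al-Fitr
2017-06-25,muslim,Eid al-Fitr
2018-06-15,muslim,Eid al-Fitr
2019-06-04,muslim,Eid al-Fitr
2012-10-26,muslim,Eid al-Adha
2013-10-15,muslim,Eid al-Adha
2014-10-04,muslim,Eid al-Adha
2015-09-23,muslim,Eid al-Adha
2016-09-11,muslim,Eid al-Adha
2017-09-01,muslim,Eid al-Adha
2018-08-21,muslim,Eid al-Adha
2019-08-11,muslim,Eid al-Adha
2012-09-17,jewish,Rosh Hashanah
2013-09-05,jewish,Rosh Hashanah
2014-09-25,jewish,Rosh Hashanah
2015-09-14,jewish,Rosh Hashanah
2016-10-03,jewish,Rosh Hashanah
2017-09-21,jewish,Rosh Hashanah
2018-09-10,jewish,Rosh Hashanah
2019-09-30,jewish,Rosh Hashanah
2012-09-26,jewish,Yom Kippur
2013-09-14,jewish,Yom Kippur
2014-10-04,jewish,Yom Kippur
2015-09-23,jewish,Yom Kippur
2016-10-12,jewish,Yom Kippur
2017-09-30,jewish,Yom Kippur
2018-09-19,jewish,Yom Kippur
2019-10-09,jewish,Yom Kippur
2012-04-07,jewish,Passover
2013-03-26,jewish,Passover
2014-04-15,jewish,Passover
2015-04-04,jewish,Passover
2016-04-23,jewish,Passover
2017-04-11,jewish,Passover
2018-03-31,jewish,Passover
2019-04-20,jewish,Passover
2012-12-09,jewish,Hanukkah
2013-11-28,jewish,Hanukkah
2014-12-17,jewish,Hanukkah
2015-12-07,jewish,Hanukkah
2016-12-25,jewish,Hanukkah
2017-12-13,jewish,Hanukkah
2018-12-03,jewish,Hanukkah
2019-12-23,jewish,Hanukkah
2012-11-13,hindu,Diwali
2013-11-03,hindu,Diwali
2014-10-23,hindu,Diwali
2015-11-11,hindu,Diwali
2016-10-30,hindu,Diwali
2017-10-19,hindu,Diwali
2018-11-07,hindu,Diwali
2019-10-27,hindu,Diwali
2012-03-08,hindu,Holi
2013-03-27,hindu,Holi
2014-03-17,hindu,Holi
2015-03-06,hindu,Holi
2016-03-24,hindu,Holi
2017-03-13,hindu,Holi
2018-03-02,hindu,Holi
2019-03-21,hindu,Holi
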