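year,region,proxy_affected,proxy_total
2005,ecoregion,441,1668
2005,brazil,301,1159
2005,paraguay,20,28
2005,bolivia,120,481
2006,ecoregion,226,1668
2006,brazil,58,1159
2006,paraguay,9,28
2006,bolivia,159,481
2007,ecoregion,431,1668
2007,brazil,232,1159
2007,paraguay,11,28
2007,bolivia,188,481
2008,ecoregion,236,1668
2008,brazil,127,1159
2008,paraguay,8,28
2008,bolivia,101,481
2009,ecoregion,231,1668
2009,brazil,139,1159
2009,paraguay,15,28
2009,bolivia,77,481
2010,ecoregion,447,1668
2010,brazil,232,1159
2010,paraguay,9,28
2010,bolivia,207,481
2011,ecoregion,163,1668
2011,brazil,127,1159
2011,paraguay,6,28
2011,bolivia,29,481
2012,ecoregion,285,1668
2012,brazil,174,1159
2012,paraguay,15,28
2012,bolivia,96,481
2013,ecoregion,140,1668
2013,brazil,116,1159
2013,paraguay,4,28
2013,bolivia,19,481
2014,ecoregion,42,1668
2014,brazil,35,1159
2014,paraguay,2,28
2014,bolivia,5,481
2015,ecoregion,163,1668
2015,brazil,93,1159
2015,paraguay,8,28
2015,bolivia,63,481
2016,ecoregion,151,1668
2016,brazil,104,1159
2016,paraguay,13,28
2016,bolivia,34,481
2017,ecoregion,187,1668
2017,brazil,139,1159
2017,paraguay,9,28
2017,bolivia,38,481
2018,ecoregion,61,1668
2018,brazil,35,1159
2018,paraguay,2,28
2018,bolivia,24,481
2019,ecoregion,513,1668
2019,brazil,267,1159
2019,paraguay,15,28
2019,bolivia,231,481
2020,ecoregion,746,1668
2020,brazil,649,1159
2020,paraguay,15,28
2020,bolivia,82,481
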