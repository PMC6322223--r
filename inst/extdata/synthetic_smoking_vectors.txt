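58 10
after -0.00961091 -0.15624665 -0.02340734 -0.33789158 0.04986640 0.31016443 -0.30479764 0.14816398 -0.15945799 -0.05314301
age -0.481411167 0.065099984 0.345420868 -0.307489223 0.147640769 0.273970141 0.349399108 -0.162032913 -0.002762175 -0.111768244
camdem -0.07117285 -0.24433379 0.70480455 -0.04708216 -0.21110337 -0.11735321 0.10476840 -0.39026406 0.60392928 -0.21341227
camgor 0.130265028 0.298457296 0.100406853 0.336327391 -0.176038060 -0.662851966 0.745567559 0.000963339 -0.156339963 -0.180617854
cammer -0.35584887 -0.02795499 -0.25557854 0.10430101 -0.50944921 0.05925879 0.42228676 0.19771051 0.08699970 0.36721725
cigrettes -0.01806624 0.01582787 0.60715762 -0.39750565 0.15836587 0.41271781 0.10458013 0.32380493 -0.39672311 0.43182850
daily 0.15241759 0.01480559 -0.46252766 -0.66610114 0.22344585 -0.43114279 -0.17147913 -0.50327605 -0.42997460 -0.54974417
day 0.01889089 0.12147769 -0.27598431 0.69849367 -0.23429280 -0.07000997 -0.35341160 -0.31031666 -0.14476657 -0.12401666
demlun -0.21973698 0.24867109 -0.23611709 0.31334602 0.01810097 -0.18173722 -0.18869618 0.35788831 -0.24824328 -0.28386938
demris -0.66616669 -0.44159690 -0.16413941 -0.28953649 -0.40902097 -0.43491647 0.06995748 -0.05709815 0.12170836 -0.42434429
dependence 0.50533947 -0.48735631 0.04415225 -0.28774033 0.51018660 0.14491333 0.28859844 -0.36233588 -0.15302923 0.20589168
finbal -0.27800034 0.02167863 0.31929100 -0.01872431 0.26052146 -0.08236533 -0.02555803 0.43989242 -0.10111383 0.25955250
for -0.079954258 -0.312454643 0.244089445 -0.163701997 -0.572702425 -0.171262356 0.003774531 -0.236469681 -0.275091571 0.225887280
forty 0.32339828 0.13627161 -0.17388010 0.02818526 -0.14537982 0.29160778 0.13260904 0.26001661 0.06445466 0.06452172
gormer 0.24353206 0.28336047 -0.27431611 -0.44468907 -0.37010280 0.54858933 0.38219762 -0.17724806 -0.04085724 -0.29345076
heavy 0.71618525 0.16465094 0.08530832 -0.00261403 -0.04213779 -0.18508061 -0.16312670 0.58562860 0.24503350 0.11858649
helmer 0.46967249 0.08256771 0.19110013 0.27345979 0.16949197 -0.63551167 0.17156407 -0.34794809 0.39378682 0.01015878
helpor -0.5218985549 -0.0699803122 0.0001698221 -0.2134154122 0.1467067972 0.3239694052 -0.2144686428 -0.2570496342 0.1923321962 -0.5347797934
lunbal 0.01110926 0.07152944 0.16104334 -0.02550732 -0.02721145 0.13433759 -0.17786276 -0.47912085 -0.13045045 0.55432365
lunris -0.28317379 0.55083990 0.19542682 -0.15540235 0.42431842 0.30241468 0.07657905 -0.32251314 -0.03292911 -0.44253066
many -0.023903260 0.063344185 0.631966989 -0.281542185 -0.207271981 -0.473909948 -0.306547598 0.245951358 0.009910134 0.536028528
merbal 0.27197004 -0.44675149 0.15132189 0.13460071 -0.14450212 0.07378617 -0.41629193 -0.20039972 0.29358112 0.07312589
merpor -0.13011747 0.10531398 0.18130441 -0.05345330 0.01544232 0.28382191 -0.38906432 -0.16857912 0.28897087 -0.60623219
nciotine 0.03544482 0.25794970 0.15583374 0.19523220 -0.24924210 -0.01394444 -0.46447040 0.33989819 -0.47487539 0.43894378
nicotine -0.022445125 0.187489161 0.088026926 0.186764568 -0.259554859 -0.008311912 -0.423333429 0.402455056 -0.520048821 0.412703002
no 0.29263876 -0.03143214 0.38372740 -0.15166350 -0.29064734 0.07962807 -0.54094209 -0.24593557 -0.03444857 -0.25740189
noted -0.05729051 -0.16956695 0.71016189 0.27375581 -0.04137796 0.11155775 0.25448838 0.11017494 -0.19032146 -0.10083120
one -0.49997722 -0.32839701 -0.13861534 0.48242136 0.23398961 -1.02563110 -0.01917006 0.04140064 -0.26180870 0.16123539
pack -0.067490121 -0.554163116 0.498373021 -0.084440984 0.013485048 -0.001888458 -0.137155311 -0.130860081 -0.118674792 -0.200874912
patient -0.21079089 0.22451157 0.18734928 0.21342851 0.32258499 0.15220253 -0.41570723 -0.25431123 -0.16845817 -0.08363945
per -0.30260178 0.36688228 -0.55530513 -0.05937210 -0.45133075 -0.35165269 -0.26076056 0.29993908 0.22125494 -0.09083294
porgor 0.569120920 0.553090242 -0.282216327 -0.005761161 -0.199340984 0.355174730 0.927771863 -0.130107271 0.188480620 -0.390547101
pridem 0.15601256 0.19109371 0.48030423 0.01099209 0.32527825 0.04410696 -0.14723087 0.44306349 -0.50503544 0.20438790
prigor -0.072260284 -0.434697891 0.008387618 -0.414633444 0.355502263 -0.197984999 -0.042140307 -0.330283970 -0.006251655 0.004719935
prinal 0.58164037 -0.14073598 0.48486552 0.18572230 -0.67772611 -0.01453155 -0.10563434 -0.71193654 0.40874910 0.30837975
regularly -0.38360598 0.41331137 -0.17637109 -0.46533029 -0.35809849 -0.13440750 0.04368369 -0.24612928 0.05249040 0.15178449
risbal -0.09850117 0.55514220 -0.33110188 0.82974420 -0.40718251 0.44107049 -0.08720733 -0.61108810 -0.01906857 0.22175267
risgor 0.32892988 0.08389553 -0.01462158 -0.40013444 0.41205226 -0.00793261 0.02497544 0.50898506 -0.01103695 -0.42044380
rislun 0.49375584 0.15602040 -0.21936243 -0.33731085 0.13549770 -0.01425069 0.44238623 -0.47934558 -0.03987576 -0.42819818
rismer 0.33668742 -0.19686379 0.25733423 0.17510781 -0.08335671 -0.52696010 0.13686792 0.27619017 -0.21897593 0.36926778
smoikng 0.59193960 -0.12207147 -0.31232649 -0.12588543 -0.35628569 0.08018857 0.17817511 0.01110607 0.29892877 0.01889656
smokes 0.13884783 -0.13716423 0.17712627 0.43854879 -0.20858917 -0.67042465 -0.07729383 -0.34851736 -0.11300687 0.21509825
sulpor -0.15162176 0.67526550 0.41748318 0.24092948 0.11860847 -0.09101002 -0.44398861 -0.01195352 0.65850456 -0.10493896
sulris -0.30723944 0.05127982 -0.41848732 0.50257347 0.68558566 0.09883274 -0.40719573 0.15404207 0.03918832 0.08680122
tammer 0.16903972 0.89586969 -0.06903248 0.46208069 0.59381072 -0.32818474 0.19991600 0.06291231 0.43720990 0.33363220
tamnal -0.23717238 -0.21413057 0.20769764 0.45709080 0.59780535 0.41283305 -0.41575728 -0.07857990 0.16329971 0.08270486
tobacc 0.116220857 -0.006145552 0.083451463 -0.297281130 -0.048021053 0.086765761 -0.118058754 0.332704522 -0.575630430 0.515977096
tobacco 0.182714151 0.033257377 0.167130272 -0.183487804 0.006306203 0.033126212 -0.093888486 0.303943281 -0.548334294 0.418269100
tormer 0.1678721 -0.6958467 0.4047445 -0.6052898 0.1054243 -0.0617839 0.1327987 -0.4916981 0.3756871 0.7359945
torris -0.12319392 0.29852531 0.23959241 -0.44049396 0.76966980 0.41032162 -0.13197843 -0.19872241 0.06081238 0.17467544
use -0.16880018 0.40357831 -0.27411984 -0.57777792 0.12399146 0.29479801 -0.06373307 -0.08067738 -0.24514971 -0.28208672
uses -0.009834689 0.236624190 0.222158495 0.091423884 -0.206368393 0.467352167 -0.337542643 -0.517332430 0.063852573 -0.031826433
wexlun 0.08571670 0.02173700 -0.29779581 -0.98631492 0.10428502 -0.27257993 0.07096399 -0.16400755 -0.18133751 -0.34657025
yambal 0.205023951 -0.054537897 0.005540528 -0.530527140 0.001936529 0.098712827 0.559775302 0.254479139 0.013501094 -0.238340295
yamdem 0.01256325 -0.05103496 -0.25563380 0.09601694 0.15031040 0.09979834 0.04603715 0.01724960 0.01803183 0.36172102
years 0.13025474 0.14540406 0.18052452 0.23290449 0.06970211 0.34912530 0.07748300 -0.13001759 0.06311278 0.37823391
zorlun -0.37248932 0.38402969 0.63121327 0.02530901 0.00662345 -0.23914264 -0.03196958 0.07186457 0.23087737 0.35582892
zorpor -0.75308316 -0.34181568 -0.17600837 0.37736143 0.04989056 0.45048367 -0.05497228 0.04218034 0.36544005 -0.40039805
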