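design,diameter,plaque,mean,sem,n
MEGATRON_10,3.5,heterogeneous,0.06519640603507915,0.0032972607472849195,4
MEGATRON_10,3.5,neutral,0.0657557700037087,0.0034786605752347953,4
MEGATRON_10,3.5,soft,0.04880219738680041,0.005241595124316766,4
MEGATRON_10,3.5,stiff,0.08510709523737676,0.004119949016496473,4
MEGATRON_10,3.5,very_soft,0.026684292967975524,0.0038613484515925053,4
MEGATRON_10,3.5,very_stiff,0.09571311029965372,0.0016793660070451408,4
MEGATRON_10,4.5,heterogeneous,0.15521106555585346,0.0047280539640532394,4
MEGATRON_10,4.5,neutral,0.17614395739954866,0.00377578425766768,4
MEGATRON_10,4.5,soft,0.15843074817831343,0.004990350626591346,4
MEGATRON_10,4.5,stiff,0.19407659935830263,0.0033245554272983966,4
MEGATRON_10,4.5,very_soft,0.1431444220487397,0.004605996359142989,4
MEGATRON_10,4.5,very_stiff,0.19742941463158004,0.002606057952219615,4
MEGATRON_10,5,heterogeneous,0.23988103645841485,0.012317115353006712,4
MEGATRON_10,5,neutral,0.25378155187698537,0.010114593305499471,4
MEGATRON_10,5,soft,0.247053256632065,0.011303890181729045,4
MEGATRON_10,5,stiff,0.25378007259473756,0.009921545376640317,4
MEGATRON_10,5,very_soft,0.24366844232925033,0.011914294369162706,4
MEGATRON_10,5,very_stiff,0.24366745184879102,0.009803373550344508,4
MEGATRON_12,3.5,heterogeneous,0.06783289601057652,0.003650218694968196,4
MEGATRON_12,3.5,neutral,0.0700420687083172,0.0037458022188834594,4
MEGATRON_12,3.5,soft,0.047830873016184286,0.004853876792112231,4
MEGATRON_12,3.5,stiff,0.0880970961698915,0.003580959939077165,4
MEGATRON_12,3.5,very_soft,0.02551129388656666,0.0036670635329250955,4
MEGATRON_12,3.5,very_stiff,0.10444492596390526,0.0033646230451908165,4
MEGATRON_12,4.5,heterogeneous,0.1609242604779868,0.003642152136965015,4
MEGATRON_12,4.5,neutral,0.18078054019600354,0.004226619167505677,4
MEGATRON_12,4.5,soft,0.1621992212790536,0.004375375390392058,4
MEGATRON_12,4.5,stiff,0.20449806939125376,0.004056866139454761,4
MEGATRON_12,4.5,very_soft,0.14798956266989757,0.003838792821233842,4
MEGATRON_12,4.5,very_stiff,0.21198891572526274,0.002266809146317725,4
MEGATRON_12,5,heterogeneous,0.2436084676779694,0.010633006827727618,4
MEGATRON_12,5,neutral,0.2578073311538037,0.009184891841066089,4
MEGATRON_12,5,soft,0.2496726366155173,0.010096449072306132,4
MEGATRON_12,5,stiff,0.2637453388261333,0.008648142882594023,4
MEGATRON_12,5,very_soft,0.24335399644726902,0.010475974642717926,4
MEGATRON_12,5,very_stiff,0.25312931983788767,0.00851010836246934,4
MEGATRON_9,3.5,heterogeneous,0.053128522500558426,0.001787315124909919,4
MEGATRON_9,3.5,neutral,0.055105866846681555,0.0022833967158335904,4
MEGATRON_9,3.5,soft,0.041062664962421974,0.004833437469356708,4
MEGATRON_9,3.5,stiff,0.0687463198700312,0.00355519834983302,4
MEGATRON_9,3.5,very_soft,0.02335559290282588,0.003573530848584206,4
MEGATRON_9,3.5,very_stiff,0.07628376523728915,0.0018471464593140762,4
MEGATRON_9,4.5,heterogeneous,0.13542263243025504,0.0035506191139751202,4
MEGATRON_9,4.5,neutral,0.15294185283808615,0.0031810547055600054,4
MEGATRON_9,4.5,soft,0.13611120321101466,0.003819606483046318,4
MEGATRON_9,4.5,stiff,0.1715286704180988,0.003837632777623889,4
MEGATRON_9,4.5,very_soft,0.12534048693647576,0.0032183026368298004,4
MEGATRON_9,4.5,very_stiff,0.1755727086276924,0.0026674955950204146,4
MEGATRON_9,5,heterogeneous,0.20608062410946312,0.008714286492692559,4
MEGATRON_9,5,neutral,0.2163568926447909,0.006171930690385609,4
MEGATRON_9,5,soft,0.21112102208841976,0.007837514784855304,4
MEGATRON_9,5,stiff,0.22363264259477705,0.005777392257534789,4
MEGATRON_9,5,very_soft,0.20601935028613041,0.007754016975804628,4
MEGATRON_9,5,very_stiff,0.21213748351254583,0.00663647256385642,4
SYNERGY,3.5,heterogeneous,0.04297206151915625,0.0027380029114035536,4
SYNERGY,3.5,neutral,0.04431921846819245,0.00300662021279405,4
SYNERGY,3.5,soft,0.032326975772829405,0.0032496429823928572,4
SYNERGY,3.5,stiff,0.055851346093309995,0.0014784329553688507,4
SYNERGY,3.5,very_soft,0.01890612238064874,0.002635263265897813,4
SYNERGY,3.5,very_stiff,0.055297483572832824,9.9326156181125e-4,4
SYNERGY,4.5,heterogeneous,0.11341336184597839,0.003241660339143552,4
SYNERGY,4.5,neutral,0.12472332487712795,0.003602137912193084,4
SYNERGY,4.5,soft,0.11473432711132572,0.002948341693024887,4
SYNERGY,4.5,stiff,0.14265295933355082,0.0030348458036324275,4
SYNERGY,4.5,very_soft,0.10407347585132158,0.0030820644018663516,4
SYNERGY,4.5,very_stiff,0.14663481667398248,0.002182090171866436,4
SYNERGY,5,heterogeneous,0.1712347602755042,0.006477557266187576,4
SYNERGY,5,neutral,0.18100330415166882,0.005408760031012462,4
SYNERGY,5,soft,0.1751018677721148,0.006033533606148161,4
SYNERGY,5,stiff,0.18728268852173183,0.0046338760600635465,4
SYNERGY,5,very_soft,0.1694003944340966,0.006413386759290401,4
SYNERGY,5,very_stiff,0.18005852031846828,0.004685447124278379,4
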