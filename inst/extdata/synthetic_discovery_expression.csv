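sample_id,group,hsa-miR-195,hsa-miR-210,hsa-miR-375,hsa-miR-483-3p,hsa-miR-483-5p,hsa-miR-497,hsa-miR-503,hsa-miR-508,hsa-miR-9
D01,ACA,-5.7473438628986813,-4.8364426728351191,-5.7630576563720872,-6.5291713722805440,-2.3143558344656476,-6.1260802470325117,-4.0689477402705769,-4.6402933772369330,-4.9811578638205418
D02,ACA,-4.2984564517460520,-2.0646222715518014,-5.3025599225785491,-5.9824460868148712,-1.9170545282722138,-5.2220382707322699,-4.1659957818849662,-6.7640000432716541,-2.6673280096467309
D03,ACA,-4.0728825712284724,-3.5289292906530463,-6.5891419715443114,-5.9797291024317758,-2.4048428693411061,-5.7800810217471508,-5.3753504256683122,-6.5657806120222766,-4.4298115327767924
D04,ACA,-6.4004545815742624,-4.5248777500337347,-6.3102273538811602,-4.7952722365254736,-3.5993936372241393,-6.1525335791734150,-4.1808523395112260,-5.8897102591009869,-3.6288528253000329
D05,ACA,-4.1935780109211258,-3.8337724393578476,-5.7937304471914643,-5.3204182137562910,-2.7577140202186072,-6.6884391554035680,-5.1999045644925168,-7.0551538087389858,-4.8338594613882933
D06,ACA,-3.9521401605884385,-2.3155521879449985,-5.6097468537603667,-5.4162407163489306,-2.6187412176538274,-5.5659549688512833,-4.6947447051166087,-7.1841682534628291,-3.2687197297031538
D07,ACA,-4.8098788832611561,-3.2717069143495472,-5.4166490803738689,-4.4632265955069457,-3.5713837940193081,-5.1285236642397898,-4.0865816859963573,-5.6813071460473878,-3.8439573377231291
D08,ACA,-2.8319916390949835,-2.9889188206668678,-4.5852396659078813,-3.9463794317156697,-3.4460354125746768,-5.9367506870236184,-5.4863726625122275,-6.2361859511200528,-3.4213368945638969
D09,ACA,-6.7156122420552329,-5.0256361120880015,-4.9019192755549774,-4.6265633249355496,-3.7920958580572055,-5.3772904873880343,-4.5096354649860650,-5.7297963208206859,-4.9501613070637589
D10,ACA,-4.0063660671448034,-4.5705625592080885,-5.9743583589216698,-3.8343738968881844,-3.6022838802314894,-5.3313564162353941,-6.3560888672631393,-6.1601544479647679,-5.0429031317714390
D11,ACC,-6.7577184948874738,-2.5189762103518234,-8.1968619347044651,-3.3204577402723530,0.4809256830758386,-7.5489493572604296,-2.9349421640646440,-2.5979828625186947,-2.1137806320973382
D12,ACC,-9.5889407880787374,-2.3917375019041458,-7.2102683226884778,-2.8166025205426841,-0.0734247026555437,-7.4598513440412013,-2.9117315279477509,-3.8626348876407519,-2.3754827779592702
D13,ACC,-7.1539277460601589,-2.3723294207250945,-8.5111478430676080,-3.3662658838145880,-0.4211850740438976,-6.7981708102140423,-3.2769059127577478,-3.9551273568620147,-0.4446153507256341
D14,ACC,-7.3185101899014064,-1.8914325717786689,-9.0940787747532497,-2.3681959782522775,0.0797759803008091,-8.2154478628295990,-5.2533878565760617,-2.0828561428332719,-2.2494948678404079
D15,ACC,-7.9224427936716992,-2.2637564532686341,-8.2271573675729996,-3.8272117936762058,-0.5154658048647001,-7.4620995122695675,-1.9922050136375447,-4.5962839748599045,-2.0015449613659726
D16,ACC,-7.5935571699147673,-2.5161987323188910,-8.4151503382843735,-3.2027929593011812,-1.4828083866092321,-7.6342180369963231,-4.6023331032739954,-3.1347126073710747,-1.9998815934200209
D17,ACC,-6.3225331426327429,-1.9218527310989977,-7.8522452720329063,-3.2084544040992498,-0.9476079994358955,-7.6513878178051904,-3.5921287050984638,-3.8383735582628802,-2.0749785432116106
D18,ACC,-7.5892184293554301,-2.2251735062345475,-6.0812521645736730,-3.2241984908961072,-1.5389196808821026,-8.0542128119254137,-4.4609744029901783,-3.3163327134996265,-1.0818766533623467
D19,ACC,-6.5771709576466293,-2.0348276135302186,-7.7310585358653370,-3.9301704009964205,-0.6060190392336544,-8.6756018064919047,-4.0189635950532434,-4.4447002591097124,-1.3818362163327826
D20,ACC,-8.0305842398224385,-2.0456569781727794,-8.6256478712592148,-4.1572642236899426,-1.7557882522701824,-8.9277056589544621,-2.6196261244296934,-3.0896250261309675,-1.1988228899041076
D21,NAC,-5.5025180962763969,-4.9916165539101129,-4.6288326437422853,-6.2222334533585162,-4.5998158450235849,-5.0804194719098490,-5.4410464322334740,-6.8272850520622761,-4.4656619794068213
D22,NAC,-4.3006983511316790,-4.7969845184943054,-6.2540984171699705,-6.5090021278562489,-2.7193773155391021,-5.4159090246626285,-7.2190425671546485,-6.3156431554394601,-4.8570965779216024
D23,NAC,-3.0460469837372059,-4.9560100576579629,-4.5882744884913045,-6.2498304069444508,-4.6503467145582924,-4.4820397296041463,-4.6868885355292988,-7.5402689725892138,-7.0924280640027568
D24,NAC,-4.3729340858383559,-4.7370763570160257,-4.9772173816787166,-6.2114678573672641,-5.5448428614019321,-5.4314616754127627,-5.9148327953510673,-7.3592594979376749,-3.5682931236031479
D25,NAC,-4.2223319496687708,-6.2586162442722753,-4.5533486304538684,-5.8263261740770496,-4.7131313421930159,-4.4753626204754227,-5.8674257834868762,-6.8308982268977410,-4.6613674708185364
D26,NAC,-4.1546664390553865,-5.3900727316635013,-3.9620493903804572,-4.5967876421739007,-3.7277678748547096,-5.2031525005719850,-5.5289856732741107,-6.0533459189601366,-3.7711695436170736
D27,NAC,-4.4131680176955186,-5.1131746661849746,-4.5169414898785902,-7.2432260559816264,-3.8992974315008837,-5.7191151729153340,-6.1248013888185504,-7.2671626048547147,-5.5265988113068190
D28,NAC,-3.9932511192683009,-4.6953011426377600,-5.5954109906563403,-6.0821358555950660,-2.9528790890879506,-5.8359071145205661,-5.8536513385112450,-6.6966070216373055,-4.2985598512631000
D29,NAC,-4.7024422780163846,-4.8424358705344943,-5.4720025726657511,-5.6528951753128887,-4.9525803408848255,-5.3924083647565091,-6.4789789871618666,-7.4458093374917311,-5.2481080910387234
D30,NAC,-4.4353671662286303,-4.3807607483644517,-5.3558604000435537,-4.6521696639043881,-3.3079076634100808,-5.1997361047742565,-5.6558537108205620,-7.3746235009505696,-6.3750887737678283
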