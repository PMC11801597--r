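# pvsignal drug-normalization dictionary
# Format: pattern<TAB>canonical ; '#' starts a comment line.
# Patterns are cleaned (case folding, dose/salt/formulation token
# stripping) before matching, so "ATORVASTATIN CALCIUM 20MG TABLET"
# matches the "atorvastatin" pattern. Seeded with drugs reported in
# association with autoimmune-like hepatitis plus common brand names and
# salt forms; extend freely.
nitrofurantoin	nitrofurantoin
macrobid	nitrofurantoin
macrodantin	nitrofurantoin
furadantin	nitrofurantoin
minocycline	minocycline
minocin	minocycline
elbasvir	elbasvir
zepatier	elbasvir
fluvastatin	fluvastatin
lescol	fluvastatin
mogamulizumab	mogamulizumab
poteligeo	mogamulizumab
aldesleukin	aldesleukin
proleukin	aldesleukin
interleukin-2	aldesleukin
propylthiouracil	propylthiouracil
hydralazine	hydralazine
apresoline	hydralazine
ipilimumab	ipilimumab
yervoy	ipilimumab
cemiplimab	cemiplimab
libtayo	cemiplimab
albendazole	albendazole
albenza	albendazole
nivolumab	nivolumab
opdivo	nivolumab
emtricitabine	emtricitabine
emtriva	emtricitabine
metreleptin	metreleptin
myalept	metreleptin
efavirenz	efavirenz
sustiva	efavirenz
meloxicam	meloxicam
mobic	meloxicam
atezolizumab	atezolizumab
tecentriq	atezolizumab
pembrolizumab	pembrolizumab
keytruda	pembrolizumab
atorvastatin	atorvastatin
lipitor	atorvastatin
simvastatin	simvastatin
zocor	simvastatin
olmesartan	olmesartan
olmesartan medoxomil	olmesartan
benicar	olmesartan
fenofibrate	fenofibrate
tricor	fenofibrate
doxycycline	doxycycline
vibramycin	doxycycline
doryx	doxycycline
amoxicillin/clavulanic acid	amoxicillin/clavulanic acid
amoxicillin/clavulanate	amoxicillin/clavulanic acid
amoxicillin and clavulanate	amoxicillin/clavulanic acid
augmentin	amoxicillin/clavulanic acid
interferon alfa-2b	interferon alfa-2b
intron a	interferon alfa-2b
ezetimibe	ezetimibe
zetia	ezetimibe
alemtuzumab	alemtuzumab
campath	alemtuzumab
lemtrada	alemtuzumab
nefazodone	nefazodone
serzone	nefazodone
cephalexin	cephalexin
cefalexin	cephalexin
keflex	cephalexin
ribavirin	ribavirin
rebetol	ribavirin
copegus	ribavirin
methylprednisolone	methylprednisolone
medrol	methylprednisolone
solu medrol	methylprednisolone
pravastatin	pravastatin
pravachol	pravastatin
ketoprofen	ketoprofen
orudis	ketoprofen
methimazole	methimazole
thiamazole	methimazole
tapazole	methimazole
indomethacin	indomethacin
indocin	indomethacin
acitretin	acitretin
soriatane	acitretin
terbinafine	terbinafine
lamisil	terbinafine
onasemnogene abeparvovec-xioi	onasemnogene abeparvovec-xioi
onasemnogene abeparvovec	onasemnogene abeparvovec-xioi
zolgensma	onasemnogene abeparvovec-xioi
avelumab	avelumab
bavencio	avelumab
anastrozole	anastrozole
arimidex	anastrozole
darunavir	darunavir
prezista	darunavir
mesalazine	mesalazine
mesalamine	mesalazine
asacol	mesalazine
pentasa	mesalazine
pemetrexed	pemetrexed
alimta	pemetrexed
interferon alfa-2a	interferon alfa-2a
roferon a	interferon alfa-2a
durvalumab	durvalumab
imfinzi	durvalumab
daclizumab	daclizumab
zinbryta	daclizumab
rosuvastatin	rosuvastatin
crestor	rosuvastatin
irbesartan	irbesartan
avapro	irbesartan
bosentan	bosentan
tracleer	bosentan
lamivudine	lamivudine
epivir	lamivudine
# frequently co-reported drugs outside the ranked-signal list
adalimumab	adalimumab
humira	adalimumab
infliximab	infliximab
remicade	infliximab
interferon beta-1a	interferon beta-1a
avonex	interferon beta-1a
rebif	interferon beta-1a
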