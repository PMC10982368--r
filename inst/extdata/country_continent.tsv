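country	continent
US	North America
CA	North America
MX	North America
UNITED STATES	North America
UNITED STATES OF AMERICA	North America
CANADA	North America
MEXICO	North America
GB	Europe
ES	Europe
FR	Europe
DE	Europe
IT	Europe
NL	Europe
PL	Europe
SE	Europe
PT	Europe
IE	Europe
BE	Europe
CH	Europe
AT	Europe
DK	Europe
NO	Europe
FI	Europe
GR	Europe
GREAT BRITAIN	Europe
UNITED KINGDOM	Europe
SPAIN	Europe
FRANCE	Europe
GERMANY	Europe
ITALY	Europe
NETHERLANDS	Europe
JP	Asia
CN	Asia
KR	Asia
IN	Asia
TW	Asia
TH	Asia
SG	Asia
IL	Asia
SA	Asia
JAPAN	Asia
CHINA	Asia
KOREA, REPUBLIC OF	Asia
INDIA	Asia
BR	South America
AR	South America
CL	South America
CO	South America
PE	South America
BRAZIL	South America
ARGENTINA	South America
AU	Oceania
NZ	Oceania
AUSTRALIA	Oceania
NEW ZEALAND	Oceania
ZA	Africa
NG	Africa
EG	Africa
KE	Africa
MA	Africa
SOUTH AFRICA	Africa
NIGERIA	Africa
EGYPT	Africa
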