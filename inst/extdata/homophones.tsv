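# Curated digit/word confusion dictionary for general-purpose ASR output.
# One entry per line: word<TAB>digit. Case-insensitive at load time.
# Canonical digit words and numerals resolve even if absent from this file.
# Replace this file with any other word->digit list of the same format.
oh	0
o	0
owe	0
nought	0
naught	0
hero	0
zorro	0
won	1
wan	1
wun	1
run	1
want	1
to	2
too	2
tu	2
tool	2
tooth	2
true	2
due	2
tree	3
free	3
thee	3
fee	3
flee	3
thread	3
threw	3
for	4
fore	4
floor	4
form	4
ford	4
fall	4
far	4
hive	5
fife	5
fine	5
dive	5
drive	5
thrive	5
sex	6
sick	6
sicks	6
six's	6
sex's	6
stick	6
seeks	6
sax	6
heaven	7
sven	7
savan	7
seventh	7
ate	8
eat	8
hate	8
late	8
gate	8
wait	8
weight	8
hey	8
aid	8
nein	9
niner	9
line	9
mine	9
wine	9
dine	9
sign	9
nun	9
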