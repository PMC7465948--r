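Name: synthetic-heptachlor-like
Retention_time: 8.50
Num Peaks: 8
100 999; 272 820; 274 650; 237 400; 65 350; 135 300; 337 180; 339 120;

Name: synthetic-fenchlorphos-like
Retention_time: 8.51
Num Peaks: 7
285 999; 287 780; 125 600; 79 450; 109 300; 167 220; 321 150;

Name: synthetic-naphthalene-like
Retention_time: 5.19
Num Peaks: 5
128 999; 127 120; 129 110; 102 80; 64 60;

Name: synthetic-pcb28-like
Retention_time: 8.33
Num Peaks: 6
256 999; 258 970; 186 550; 151 300; 260 310; 188 180;

Name: synthetic-phthalate-like
Retention_time: 11.18
Num Peaks: 4
149 999; 167 280; 279 120; 57 200;
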