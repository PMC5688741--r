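"subject_id","entry_age","exit_age","from_state","to_state","srh_poor","male","weight"
1,55,56.4033,"W","S",0,0,1
1,56.4033,57.547,"S","W",0,0,1
1,57.547,60.9356,"W","U",0,0,1
1,60.9356,61.0776,"U","CENSORED",0,0,1
2,55,55.4695,"W","S",0,1,1
2,55.4695,55.5092,"S","W",0,1,1
2,55.5092,55.8207,"W","S",0,1,1
2,55.8207,55.8583,"S","W",0,1,1
2,55.8583,56.368,"W","S",0,1,1
2,56.368,56.5791,"S","W",0,1,1
2,56.5791,59.6127,"W","U",0,1,1
2,59.6127,60.5643,"U","E",0,1,1
3,55,60.0455,"W","S",0,0,1
3,60.0455,60.5279,"S","W",0,0,1
3,60.5279,61.6787,"W","E",0,0,1
4,55,62.2034,"W","E",0,0,1
5,55,61.233,"W","S",0,0,1
5,61.233,61.3202,"S","W",0,0,1
5,61.3202,61.6345,"W","E",0,0,1
6,55,55.3332,"W","S",0,0,1
6,55.3332,56.9594,"S","W",0,0,1
6,56.9594,61.4566,"W","E",0,0,1
7,55,57.4783,"W","S",0,0,1
7,57.4783,58.1617,"S","W",0,0,1
7,58.1617,60.2333,"W","E",0,0,1
8,55,62.9153,"W","E",0,0,1
9,55,60.2405,"W","S",0,0,1
9,60.2405,61.4309,"S","W",0,0,1
9,61.4309,61.436,"W","E",0,0,1
10,55,55.5237,"W","S",0,0,1
10,55.5237,55.7121,"S","W",0,0,1
10,55.7121,55.7313,"W","U",0,0,1
10,55.7313,55.7886,"U","W",0,0,1
10,55.7886,57.3109,"W","S",0,0,1
10,57.3109,58.1186,"S","W",0,0,1
10,58.1186,59.7682,"W","S",0,0,1
10,59.7682,59.9555,"S","W",0,0,1
10,59.9555,65,"W","CENSORED",0,0,1
11,55,55.3475,"W","S",0,0,1
11,55.3475,56.8123,"S","W",0,0,1
11,56.8123,59.4978,"W","U",0,0,1
11,59.4978,60.3136,"U","E",0,0,1
12,55,56.617,"W","S",0,0,1
12,56.617,56.9858,"S","W",0,0,1
12,56.9858,58.1388,"W","S",0,0,1
12,58.1388,58.4913,"S","W",0,0,1
12,58.4913,62.0721,"W","E",0,0,1
13,55,60.3705,"W","E",0,0,1
14,55,62.702,"W","E",0,0,1
15,55,55.7672,"W","U",0,1,1
15,55.7672,55.8813,"U","W",0,1,1
15,55.8813,61.2807,"W","S",0,1,1
15,61.2807,61.3869,"S","W",0,1,1
15,61.3869,61.8415,"W","E",0,1,1
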