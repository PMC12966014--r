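block	chromosome	order
A	ACK1	1
B	ACK1	2
C	ACK1	3
D	ACK2	1
E	ACK2	2
F	ACK3	1
G	ACK3	2
H	ACK3	3
I	ACK4	1
J	ACK4	2
K	ACK5	1
L	ACK5	2
M	ACK5	3
O	ACK6	1
Q	ACK6	2
R	ACK6	3
S	ACK7	1
T	ACK7	2
U	ACK7	3
V	ACK8	1
W	ACK8	2
X	ACK8	3
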