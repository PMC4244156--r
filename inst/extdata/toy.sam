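@HD	VN:1.6	SO:coordinate
@SQ	SN:ref	LN:20000
G	99	ref	9351	60	100M	=	10151	900	*	*
A	99	ref	9401	60	100M	=	10206	905	*	*
H	99	ref	9651	60	100M	=	10031	480	*	*
B	99	ref	9701	60	100M	=	10111	510	*	*
F	99	ref	9801	0	100M	=	10201	500	*	*
C	73	ref	9931	60	70M30S	=	9931	0	*	*
C	133	ref	9931	0	*	=	9931	0	*	*
D	73	ref	9951	60	100M	=	9951	0	*	*
D	133	ref	9951	0	*	=	9951	0	*	*
H	147	ref	10031	60	100M	=	9651	-480	*	*
B	147	ref	10111	60	100M	=	9701	-510	*	*
G	147	ref	10151	60	100M	=	9351	-900	*	*
F	147	ref	10201	0	100M	=	9801	-500	*	*
A	147	ref	10206	60	100M	=	9401	-905	*	*
I	99	ref	10291	60	100M	=	10711	520	*	*
E	73	ref	10351	60	100M	=	10351	0	*	*
E	133	ref	10351	0	*	=	10351	0	*	*
C	2121	ref	10401	60	70H30M	=	9931	0	*	*
I	147	ref	10711	60	100M	=	10291	-520	*	*
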