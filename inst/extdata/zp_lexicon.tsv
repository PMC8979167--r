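# Verbatim endpoint string -> trait id. The 32 abnormal-tail rows are the
# published example mapping table; curator rows cover the whole-specimen
# categories.
verbatim	curie	provenance
Malformation tail	ZP:0001129	published mapping table
tail deformation	ZP:0001129	published mapping table
malformation tail	ZP:0001129	published mapping table
length of the tail	ZP:0001129	published mapping table
caudal fin malformation	ZP:0004969	published mapping table
caudal fin malformations	ZP:0004969	published mapping table
malformed caudal fin	ZP:0004969	published mapping table
Cfin	ZP:0004969	published mapping table
cfin	ZP:0004969	published mapping table
Malformation tail fin	ZP:0004969	published mapping table
Tail End Vacuolization	ZP:0004969	published mapping table
ruffled fin	ZP:0004969	published mapping table
tail tip necrosis	ZP:0004969	published mapping table
vacuolization in end of tail	ZP:0004969	published mapping table
Curved tail	ZP:0010319	published mapping table
Slightly Curved Tail	ZP:0010319	published mapping table
bent tail tip	ZP:0010319	published mapping table
C tail	ZP:0010319	published mapping table
C-tail	ZP:0010319	published mapping table
bend tail	ZP:0010319	published mapping table
curved tail	ZP:0010319	published mapping table
curved tail tip	ZP:0010319	published mapping table
slightly curved tail	ZP:0010319	published mapping table
slight tail curve	ZP:0010319	published mapping table
tail curve	ZP:0010319	published mapping table
tail tip curve	ZP:0010319	published mapping table
tail bending	ZP:0010319	published mapping table
abnormal tail curvature	ZP:0010319	published mapping table
Possible Short Tail	ZP:0001130	published mapping table
short tail	ZP:0001130	published mapping table
possible short tail	ZP:0001130	published mapping table
reduced tail length	ZP:0001130	published mapping table
normal	normal	curator
hatched	hatched	curator
dead	ZP:0000306	curator
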