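# sugarcat-phenotypes v1
strain	substrate	predicted	observed	flagged
MR1	Glc	plus	n	1
MR1	Nag	plus	p	0
MR1	Grt	plus	p	0
MR1	Bgl	minus	n	0
MR1	Scr	minus	n	0
MR1	Mal	plus	n	1
MR1	Ara	minus	n	0
MR1	Gal	minus	n	0
MR1	Gnt	minus	n	0
MR1	Aga	minus	n	0
MR1	Tre	minus	n	0
MR1	Mtl	minus	n	0
CN32	Glc	minus	n	0
CN32	Nag	plus	p	0
CN32	Grt	plus	p	0
CN32	Bgl	minus	n	0
CN32	Scr	minus	n	0
CN32	Mal	minus	n	0
CN32	Ara	plus	p	0
CN32	Gal	minus	n	0
CN32	Gnt	minus	n	0
CN32	Aga	minus	n	0
CN32	Tre	minus	n	0
CN32	Mtl	minus	n	0
W3181	Glc	minus	n	0
W3181	Nag	plus	p	0
W3181	Grt	plus	p	0
W3181	Bgl	minus	n	0
W3181	Scr	minus	n	0
W3181	Mal	minus	n	0
W3181	Ara	plus	nd	0
W3181	Gal	minus	n	0
W3181	Gnt	minus	nd	0
W3181	Aga	minus	nd	0
W3181	Tre	minus	n	0
W3181	Mtl	minus	nd	0
OS155	Glc	plus	p	0
OS155	Nag	plus	p	0
OS155	Grt	plus	p	0
OS155	Bgl	plus	p	0
OS155	Scr	plus	p	0
OS155	Mal	plus	p	0
OS155	Ara	minus	n	0
OS155	Gal	minus	n	0
OS155	Gnt	plus	p	0
OS155	Aga	minus	n	0
OS155	Tre	minus	n	0
OS155	Mtl	minus	n	0
OS185	Glc	plus	p	0
OS185	Nag	plus	p	0
OS185	Grt	plus	p	0
OS185	Bgl	plus	p	0
OS185	Scr	plus	p	0
OS185	Mal	plus	p	0
OS185	Ara	minus	nd	0
OS185	Gal	plus	p	0
OS185	Gnt	plus	nd	0
OS185	Aga	minus	nd	0
OS185	Tre	minus	n	0
OS185	Mtl	minus	nd	0
OS195	Glc	plus	p	0
OS195	Nag	plus	p	0
OS195	Grt	plus	p	0
OS195	Bgl	plus	p	0
OS195	Scr	plus	p	0
OS195	Mal	plus	p	0
OS195	Ara	minus	nd	0
OS195	Gal	minus	n	0
OS195	Gnt	plus	nd	0
OS195	Aga	minus	nd	0
OS195	Tre	minus	n	0
OS195	Mtl	minus	nd	0
OS223	Glc	plus	p	0
OS223	Nag	plus	p	0
OS223	Grt	plus	p	0
OS223	Bgl	plus	p	0
OS223	Scr	plus	p	0
OS223	Mal	plus	p	0
OS223	Ara	minus	nd	0
OS223	Gal	plus	p	0
OS223	Gnt	plus	nd	0
OS223	Aga	minus	nd	0
OS223	Tre	plus	p	0
OS223	Mtl	minus	nd	0
MR7	Glc	plus	p	0
MR7	Nag	plus	p	0
MR7	Grt	plus	p	0
MR7	Bgl	minus	n	0
MR7	Scr	plus	p	0
MR7	Mal	plus	p	0
MR7	Ara	plus	p	0
MR7	Gal	minus	n	0
MR7	Gnt	minus	n	0
MR7	Aga	plus	p	0
MR7	Tre	minus	n	0
MR7	Mtl	minus	n	0
MR4	Glc	plus	p	0
MR4	Nag	plus	p	0
MR4	Grt	plus	p	0
MR4	Bgl	minus	n	0
MR4	Scr	plus	p	0
MR4	Mal	plus	p	0
MR4	Ara	plus	p	0
MR4	Gal	minus	n	0
MR4	Gnt	minus	n	0
MR4	Aga	plus	p	0
MR4	Tre	minus	n	0
MR4	Mtl	minus	n	0
ANA3	Glc	plus	p	0
ANA3	Nag	plus	p	0
ANA3	Grt	plus	p	0
ANA3	Bgl	minus	n	0
ANA3	Scr	plus	p	0
ANA3	Mal	plus	p	0
ANA3	Ara	plus	p	0
ANA3	Gal	minus	n	0
ANA3	Gnt	minus	n	0
ANA3	Aga	plus	p	0
ANA3	Tre	minus	n	0
ANA3	Mtl	minus	n	0
Sden	Glc	plus	w	0
Sden	Nag	plus	p	0
Sden	Grt	minus	n	0
Sden	Bgl	plus	p	0
Sden	Scr	minus	n	0
Sden	Mal	plus	p	0
Sden	Ara	minus	n	0
Sden	Gal	minus	n	0
Sden	Gnt	minus	n	0
Sden	Aga	minus	n	0
Sden	Tre	minus	n	0
Sden	Mtl	minus	n	0
Sfri	Glc	plus	p	0
Sfri	Nag	minus	n	0
Sfri	Grt	plus	p	0
Sfri	Bgl	plus	p	0
Sfri	Scr	plus	p	0
Sfri	Mal	plus	p	0
Sfri	Ara	minus	n	0
Sfri	Gal	minus	n	0
Sfri	Gnt	minus	n	0
Sfri	Aga	minus	n	0
Sfri	Tre	plus	p	0
Sfri	Mtl	plus	n	1
PV4	Glc	plus	w	0
PV4	Nag	plus	p	0
PV4	Grt	plus	p	0
PV4	Bgl	minus	n	0
PV4	Scr	minus	n	0
PV4	Mal	plus	w	0
PV4	Ara	minus	n	0
PV4	Gal	plus	w	0
PV4	Gnt	minus	n	0
PV4	Aga	minus	n	0
PV4	Tre	minus	n	0
PV4	Mtl	minus	n	0
Sama	Glc	plus	p	0
Sama	Nag	plus	p	0
Sama	Grt	minus	n	0
Sama	Bgl	plus	p	0
Sama	Scr	minus	n	0
Sama	Mal	plus	p	0
Sama	Ara	minus	n	0
Sama	Gal	minus	n	0
Sama	Gnt	minus	n	0
Sama	Aga	plus	p	0
Sama	Tre	minus	n	0
Sama	Mtl	minus	n	0
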