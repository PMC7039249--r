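pdb_id	family	length	provenance
1DUR	fd4	54	reported
2FDN	fd4	55	constructed
1CLF	fd4	55	constructed
1FXD	fd4	58	constructed
1VJW	fd4	60	constructed
1FXR	fd4	64	constructed
1SJ1	fd4	62	constructed
4ID8	fd4	59	constructed
1BC6	fd4	64	constructed
1BWE	fd4	66	constructed
1H98	fd4	63	constructed
4KT0	fd4	85	constructed
1RGV	fd4	88	constructed
1JB0	fd4	81	constructed
1IQZ	fd4	89	constructed
1BLU	fd4	90	constructed
2FGO	fd4	92	constructed
2ZVS	fd4	94	constructed
2VKR	fd4	96	constructed
1XER	fd4	103	constructed
2V2K	fd4	105	constructed
7FDR	fd4	106	reported
1L5P	fd2	97	constructed
4ITK	fd2	97	constructed
1WRI	fd2	97	constructed
1AWD	fd2	98	constructed
2MH7	fd2	98	constructed
1FRR	fd2	99	constructed
4ZHO	fd2	97	constructed
3AV8	fd2	98	constructed
1PFD	fd2	99	constructed
1OFF	fd2	97	constructed
5H57	fd2	99	constructed
3AB5	fd2	98	constructed
1ROE	fd2	97	constructed
1A70	fd2	99	constructed
4FXC	fd2	98	constructed
3B2G	fd2	97	constructed
3B2F	fd2	99	constructed
1RFK	fd2	98	constructed
1JQ4	fd2	97	constructed
1IUE	fd2	99	constructed
1FRD	fd2	98	constructed
1CZP	fd2	99	constructed
2WLB	fd2	127	constructed
3LXF	fd2	127	constructed
1B9R	fd2	128	constructed
1UWM	fd2	128	constructed
1PDX	fd2	128	constructed
1M2D	fd2	128	constructed
1I7H	fd2	128	constructed
3AH7	fd2	128	constructed
2MJD	fd2	128	constructed
2MJ3	fd2	128	constructed
2Y5C	fd2	128	constructed
5FFI	fd2	128	constructed
3P1M	fd2	128	constructed
1E0Z	fd2	128	reported
1DOI	fd2	128	constructed
1AYF	fd2	128	constructed
2FZ5	fld	147	constructed
1FLD	fld	147	constructed
4HEQ	fld	147	constructed
2HNA	fld	148	constructed
2FX2	fld	148	constructed
3F6R	fld	146	constructed
3KAP	fld	148	constructed
5B3L	fld	147	constructed
4OXX	fld	146	constructed
1FUE	fld	168	constructed
2BMV	fld	170	constructed
2W5U	fld	169	constructed
1CZH	fld	166	constructed
1FLV	fld	166	constructed
1OBO	fld	167	constructed
2MT9	fld	168	constructed
2FCR	fld	168	constructed
1AG9	fld	169	constructed
1YOB	fld	170	constructed
2WC1	fld	172	constructed
2ARK	fld	184	reported
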