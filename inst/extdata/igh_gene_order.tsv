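# Approximate human IGH locus order (3'-most J first within each type is
# NOT used: genes are listed 5' to 3' along the locus as conventionally
# displayed). Derived from the public IMGT gene tables for Homo sapiens;
# marked approximate - users can supply their own ordering file with the
# same two columns.
locus	gene
IGH	IGHV7-81
IGH	IGHV3-74
IGH	IGHV3-73
IGH	IGHV3-72
IGH	IGHV2-70
IGH	IGHV1-69
IGH	IGHV3-66
IGH	IGHV3-64
IGH	IGHV4-61
IGH	IGHV4-59
IGH	IGHV1-58
IGH	IGHV3-53
IGH	IGHV5-51
IGH	IGHV3-49
IGH	IGHV3-48
IGH	IGHV1-46
IGH	IGHV1-45
IGH	IGHV3-43
IGH	IGHV4-39
IGH	IGHV4-34
IGH	IGHV3-33
IGH	IGHV4-31
IGH	IGHV3-30
IGH	IGHV4-28
IGH	IGHV2-26
IGH	IGHV1-24
IGH	IGHV3-23
IGH	IGHV3-21
IGH	IGHV3-20
IGH	IGHV1-18
IGH	IGHV3-16
IGH	IGHV3-15
IGH	IGHV3-13
IGH	IGHV3-11
IGH	IGHV3-9
IGH	IGHV1-8
IGH	IGHV3-7
IGH	IGHV2-5
IGH	IGHV7-4-1
IGH	IGHV4-4
IGH	IGHV1-3
IGH	IGHV1-2
IGH	IGHV6-1
IGH	IGHD1-1
IGH	IGHD2-2
IGH	IGHD3-3
IGH	IGHD4-4
IGH	IGHD5-5
IGH	IGHD6-6
IGH	IGHD1-7
IGH	IGHD2-8
IGH	IGHD3-9
IGH	IGHD3-10
IGH	IGHD4-11
IGH	IGHD5-12
IGH	IGHD6-13
IGH	IGHD1-14
IGH	IGHD2-15
IGH	IGHD3-16
IGH	IGHD4-17
IGH	IGHD5-18
IGH	IGHD6-19
IGH	IGHD1-20
IGH	IGHD2-21
IGH	IGHD3-22
IGH	IGHD4-23
IGH	IGHD5-24
IGH	IGHD6-25
IGH	IGHD1-26
IGH	IGHD7-27
IGH	IGHJ1
IGH	IGHJ2
IGH	IGHJ3
IGH	IGHJ4
IGH	IGHJ5
IGH	IGHJ6
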