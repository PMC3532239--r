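category	phenotypic	incidental
missense	111	330
noncritical_splice_donor	5	22
noncritical_splice_acceptor	6	22
nonsense	35	19
critical_splice_donor	17	8
critical_splice_acceptor	4	1
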