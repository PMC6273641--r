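ThaBI [(KS-AT-ACP)-(KS-AT-KR-ACP)-(KS-AT-DH-KR-ACP)-(KS-AT-DH-KR-ACP)-(KS-AT-DH-KR-ACP)-Dock],
ThaBII [Dock-(KS-AT-DH-KR-ACP)-(KS-AT-DH-KR-ACP)-Dock],
ThaBIII [Dock-(KS-AT-DH-KR-ACP)-(KS-AT-KR-ACP)-(KS-AT-KR-ACP)-(KS-AT-KR-ACP)-(KS-AT-KR-ACP)-Dock],
ThaBIV [Dock-(KS-AT-KR-ACP)-(KS-AT-KR-ACP)-TE]
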