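## Golden-image digests (md5 of the written PNG bytes), recorded at first
## implementation. The renderer is scalar double arithmetic with no
## threading, so identical inputs must reproduce these bit-for-bit.

GOLDEN_CAPSID_MD5 <- "7a011fccd55f2c8630fcb8f7197cbe56"
GOLDEN_PACKED_MD5 <- "e3c1607190b36bad2587d87e87d2af84"
GOLDEN_MEMBRANE_MD5 <- "e7812469fca31769676a1ab7612eae13"
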