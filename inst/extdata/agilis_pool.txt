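# Banding-sequence pool of Chironomus agilis (16 sequences, arms A-F mapped).
# One sequence per line: id, band runs, terminal centromere marker "C".
# A trailing "(KV)"/"(GV)" tags alternative mapping versions of the same
# sequence (arm E); versions are never mixed within one comparison and GV is
# the packaged default.
# Arm G carries two nucleolar organisers and Balbiani rings that obscure the
# banding pattern; its single banding sequence p'agiG1 has no published map
# and is kept as an unmapped placeholder.
# arms: A B C D E F G
p'agiA1 1a-2c 10a-12c 3i-2h 4d-9e 2d-g 4c-a 13a-19f C
p'agiA2 1a-2c 10a-12c 3i 6a-4d 2h-3h 6b-9e 2d-g 4c-a 13a-19f C
p'agiB1 25s-q 18n-16a 22a-r 25k-23f 15g-r 21t-i 18o-21h 25p-l 22s-23e 15f-12v C
p'agiB2 25s-q 18n-16a 22ab 23c-22s 25l-p 21h-18o 21i-t 15r-g 23f-25k 22r-c 23de 15f-12v C
p'agiB3 25s-q 18n-16a 22ab 23c-22s 25l-p 21h-18o 21i-t 15r-m 24m-23f 15g-l 24n-25k 22r-c 23de 15f-12v C
h'agiC1 1a-2c 6c-f 7a-d 16a-17a 6hg 11d-15e 8a-11c 6b-2d 17b-22g C
p'agiC2 1a-e 5b-4h 16h-a 7d-6c 2c-1f 5c-6b 11c-8a 15e-11d 6gh 17a 4g-2d 17b-22g C
p'agiD1 1a-d 4a-7g 18a-d 8a-10a 13a-11a 3g-1e 10e-b 13b-14a 20d-18e 17f-14b 21a-24g C
p'agiD2 1a-d 4a-7g 18a-d 8a-10a 13a-11a 3g-1e 10e-b 13bc 16a-17f 18e-20d 14a-13d 15e-14b 21a-24g C
p'agiD3 1a-d 4a-7g 18a-d 8a-10a 13a-11a 3g-2h 19a-20d 14a-13b 10b-e 1e-2g 18g-e 17f-14b 21a-24g C
h'agiE1 1a-3e 5a-10b 4h-3f 10c-13g C (KV)
h'agiE1 1a-3a 4c-10b 3e-b 4b-3f 10c-13g C (GV)
p'agiE2 1a-3a 4c-10b 3e-b 4b-3f 10c-e 12g-10f 13a-g C (GV)
p'agiF1 1a-d 6e-1e 7a-10d 18c-a 11a-17d 18d-23f C
p'agiF2 1a-d 6e-b 4c-6a 2a-4b 1i-e 7a-10d 18c-a 11a-17d 18d-23f C
p'agiF3 1a-d 6e-1e 7a-10d 18c-a 11a-17d 18d-21d 22e-a 23a-f C
p'agiG1 unmapped
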