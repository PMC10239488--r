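>EN synthetic endonuclease-domain reference peptide (fixed-seed stand-in)
KEGRGFMESDIELIAGVHAGGSRLLLKSKSTFFVNDSAAIAQGGQKPPHGHGTNGVDPRY
IAAAYYVDSMELPPFRELMGTELDTNLLPPSIKAVGEEGSTGKGQALSAFCPLLRALAAH
GYITSALAELAHTPLTKKLGDGVIFNVGGLDLLAPLYFENCPATLGAIIVCNILTGCKKR
YAPCNFDTHASANMPANPYALVVFFAVVLKRRAYCKLAQQTPYPTESPFS
>RT synthetic reverse-transcriptase-domain reference peptide (fixed-seed stand-in)
HFIDISTMGPIRTNFLIFYVAEENLPGQISQPTKIFAMLVQVNGAASCMEVFRTLPLLFI
AIPNELFFSEFAYSCEGVIPSLGMHTMTVLNAEPASIKTAPGGDNAERVIGGHPLKANIV
GLSKADDKRSTDFGVDTGDVYCMAVLNLKRIHDGQDSDVTPTDTPDGSKIDDVHNGKLGK
HAQCELGQLCSVSAADPKKFHLDEFLVSLTIMHLDELIIGQGQTMKVNVLRMYDLKRKRG
QRVKLSAPTTHDGINSPDTQ
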