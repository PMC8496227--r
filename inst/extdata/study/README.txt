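Place the original study's supplementary data here to run the two
reproduction checks in tests/testthat/test-acceptance.R (the package does
not download or redistribute third-party data):

  alignment.fasta  in-frame codon alignment of the parent gene and its
                   retrocopy orthologs (the study's supplementary sequence
                   archive), taxa named as in tree.nwk
  tree.nwk         newick tree for that alignment with the retrocopy clade
                   branches marked as foreground by a "#1" label suffix
  ddg.tsv          tab-delimited per-substitution free-energy table with
                   columns site, wt_aa, mut_aa, ddg_bind, ddg_fold
  structure.pdb    coordinates of the two-chain complex (chains A and B)
                   the ddg table refers to

Without these files the two checks fail with a pointer to this directory.
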