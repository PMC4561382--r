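# Synthetic carrier transcripts that place the printed probe/insert
# sequences at their reported transcript coordinates, with a G-free filler
# and an AUG anchoring the published reading frame (codons from 222 for the
# MLL1 probe region, from 262 for the reporter insert). These are synthetic
# stand-ins for the unreleased transcripts: only the embedded printed
# region and the frame anchor are faithful.

g_free_filler <- function(n) substr(strrep("ACU", ceiling(n / 3)), 1, n)

fixture_seq <- function(name) {
  fx <- probe_fixtures()
  fx$sequence[fx$name == name]
}

# MLL1 probe occupies 220-258; cds_start = 3 puts codon starts on 222.
mll1_carrier <- function(tail = 30L) {
  probe <- fixture_seq("mll1_probe")
  prefix <- paste0("AC", "AUG", g_free_filler(214L))
  transcript_record("KMT2A_synthetic", paste0(prefix, probe, g_free_filler(tail)),
                    cds_start = 3L)
}

# reporter insert occupies 262-318; cds_start = 1 puts codon starts on 262.
pgl3_carrier <- function(tail = 30L) {
  ins <- fixture_seq("pgl3_mll4_insert")
  prefix <- paste0("AUG", g_free_filler(258L))
  transcript_record("pGL3_MLL4_synthetic", paste0(prefix, ins, g_free_filler(tail)),
                    cds_start = 1L)
}
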