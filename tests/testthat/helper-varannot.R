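# Hand-constructed mini-genome: two genes on chrT (18 kb).
#   geneA (+): 5'UTR 6101-6110, CDS exon1 6111-6122 (ATG TAC GGA TGG),
#     intron 6123-6142 (GT..AG), CDS exon2 6143-6151 (AAA CCC TAA),
#     3'UTR 6152-6159.
#   geneB (-): single CDS 11761-11769; transcript reads ATG GAT TAA.
hand_world <- function() {
  pad <- function(n) strrep("T", n)
  chrT <- paste0(pad(6100),
                 "CCCCCCCCCC",            # 5'UTR of geneA
                 "ATGTACGGATGG",          # CDS exon1
                 "GT", strrep("A", 16), "AG",  # intron
                 "AAACCCTAA",             # CDS exon2
                 "GGGGGGGG",              # 3'UTR
                 pad(5601),
                 "TTAATCCAT",             # geneB, revcomp of ATGGATTAA
                 pad(6231))
  genome <- Biostrings::DNAStringSet(c(chrT = chrT))
  genes <- data.frame(gene_id = c("geneA", "geneB"), chrom = "chrT",
                      strand = c("+", "-"), start = c(6101L, 11761L),
                      end = c(6159L, 11769L))
  exons <- data.frame(gene_id = c("geneA", "geneA", "geneB"),
                      chrom = "chrT", start = c(6101L, 6143L, 11761L),
                      end = c(6122L, 6159L, 11769L))
  cds <- data.frame(gene_id = c("geneA", "geneA", "geneB"), chrom = "chrT",
                    start = c(6111L, 6143L, 11761L),
                    end = c(6122L, 6151L, 11769L), phase = 0L)
  list(models = gene_models(genes, exons, cds), genome = genome)
}

hand_variants <- function() {
  v <- function(pos, ref, alt, consequence, gene) {
    data.frame(chrom = "chrT", pos = pos, ref = ref, alt = alt,
               expected = consequence, gene = gene,
               stringsAsFactors = FALSE)
  }
  rbind(
    v(6111L, "A", "C", "start_lost", "geneA"),       # ATG -> CTG
    v(6116L, "C", "A", "stop_gained", "geneA"),      # TAC -> TAA
    v(6122L, "G", "C", "missense", "geneA"),         # TGG -> TGC
    v(6114L, "T", "C", "missense", "geneA"),         # TAC -> CAC
    v(6119L, "A", "G", "synonymous", "geneA"),       # GGA -> GGG
    v(6151L, "A", "C", "stop_lost", "geneA"),        # TAA -> TAC
    v(6151L, "A", "G", "stop_retained", "geneA"),    # TAA -> TAG
    v(6144L, "AAC", "A", "frameshift", "geneA"),     # 2 bp CDS deletion
    v(6144L, "AACC", "A", "inframe_indel", "geneA"), # 3 bp CDS deletion
    v(6123L, "G", "A", "splice_donor", "geneA"),
    v(6142L, "G", "T", "splice_acceptor", "geneA"),
    v(6130L, "A", "C", "intron", "geneA"),
    v(6105L, "C", "T", "utr", "geneA"),
    v(5000L, "T", "A", "upstream", "geneA"),
    v(6300L, "T", "G", "downstream", "geneA"),
    v(500L, "T", "C", "intergenic", NA),
    v(11765L, "T", "A", "missense", "geneB"),        # GAT -> GTT
    v(11764L, "A", "G", "synonymous", "geneB"),      # GAT -> GAC
    v(11767L, "C", "T", "start_lost", "geneB"),      # ATG -> ATA
    v(17500L, "T", "G", "intergenic", NA))
}
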