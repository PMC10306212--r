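# In-code fixture builders shared across test files.

write_vcf_fixture <- function(lines) {
  path <- tempfile(fileext = ".vcf")
  writeLines(lines, path)
  path
}

# minimal two-sample VCF with configurable body rows
vcf_text <- function(body, samples = c("S1", "S2")) {
  c("##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    body)
}

vcf_row <- function(chrom, pos, ref, alt, filter, gts) {
  paste(c(chrom, pos, ".", ref, alt, ".", filter, ".", "GT", gts),
        collapse = "\t")
}

write_control_fixture <- function(df) {
  path <- tempfile(fileext = ".tsv")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# a small fully-specified annotation table
anno_row <- function(chrom, pos, ref, alt, gene,
                     consequence = "stop_gained", cadd = 35,
                     af_gnomad = NA_real_, af_alfa = NA_real_,
                     filter = "PASS") {
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt, gene = gene,
             consequence = consequence, cadd_phred = cadd,
             af_gnomad_nfe = af_gnomad, af_alfa_eur = af_alfa,
             filter = filter, stringsAsFactors = FALSE)
}
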