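# Readers and writers for the standard formats the pipeline touches.
# FASTA/FASTQ go through Biostrings; VCF reading goes through vcfR.
# VCF writing emits minimal plain text (the simulator's fixtures must
# be byte-stable and uncompressed).

#' Read and write FASTA
#'
#' Thin wrappers over Biostrings keeping the package's working
#' representation (named character vectors of DNA strings).
#'
#' @param path File path.
#' @param seqs Named character vector of DNA strings.
#' @return `read_fasta()` returns a named character vector;
#'   `write_fasta()` returns `path` invisibly.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' @rdname read_fasta
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Read and write FASTQ
#'
#' The simulator emits quality-less reads; `write_fastq()` records a
#' constant placeholder quality (`I`, Q40) for every base.
#'
#' @param path File path.
#' @param reads Character vector of reads.
#' @param ids Optional read names (default `read1`, `read2`, ...).
#' @return `read_fastq()` returns a character vector of reads;
#'   `write_fastq()` returns `path` invisibly.
#' @export
read_fastq <- function(path) {
  as.character(Biostrings::readDNAStringSet(path, format = "fastq"))
}

#' @rdname read_fastq
#' @export
write_fastq <- function(reads, path,
                        ids = paste0("read", seq_along(reads))) {
  x <- Biostrings::DNAStringSet(reads)
  names(x) <- ids
  Biostrings::writeXStringSet(
    x, path, format = "fastq",
    qualities = Biostrings::BStringSet(strrep("I", nchar(reads))))
  invisible(path)
}

#' Write a variant cohort as VCF plus flank FASTA
#'
#' Emits a minimal VCF (CHROM/POS/ID/REF/ALT/QUAL/FILTER/INFO with a
#' `CLNSIG` key for the label) and a FASTA of the per-variant flank
#' sequences keyed by contig, the pair that [read_variant_cohort()]
#' reads back.
#'
#' @param variants A [variant_table()] tibble.
#' @param vcf_path,fasta_path Output paths.
#' @return Invisibly, `c(vcf_path, fasta_path)`.
#' @export
write_variant_cohort <- function(variants, vcf_path, fasta_path) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=CLNSIG,Number=1,Type=String,Description=\"Clinical significance label\">",
    paste0("##contig=<ID=", unique(variants$contig), ">"),
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\t.\tCLNSIG=%s",
                  variants$contig, variants$pos, variants$ref,
                  variants$alt,
                  ifelse(is.na(variants$label), ".", variants$label))
  writeLines(c(header, body), vcf_path)
  write_fasta(setNames(variants$flank, variants$contig), fasta_path)
  invisible(c(vcf_path, fasta_path))
}

#' Read a variant cohort from VCF plus reference FASTA
#'
#' Reads SNVs (CHROM, POS, REF, ALT, optional `CLNSIG` INFO label)
#' with vcfR and extracts a flank of the requested radius from the
#' FASTA sequence of each variant's contig.
#'
#' @param vcf_path VCF file.
#' @param fasta_path FASTA file with the contig sequences.
#' @param flank_radius Flank radius in nt (default 30). Variants too
#'   close to a contig end to supply a full flank are dropped with a
#'   warning.
#' @return A [variant_table()] tibble (with `pos` relative to the
#'   original contig and the flank centred on the variant).
#' @export
read_variant_cohort <- function(vcf_path, fasta_path, flank_radius = 30L) {
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fx <- vcfR::getFIX(vcf)
  fx <- as_tibble(as.data.frame(fx, stringsAsFactors = FALSE))
  label <- vcfR::extract.info(vcf, "CLNSIG")
  seqs <- read_fasta(fasta_path)
  pos <- as.integer(fx$POS)
  contig <- fx$CHROM
  snv <- nchar(fx$REF) == 1 & nchar(fx$ALT) == 1
  ok <- snv & contig %in% names(seqs) &
    pos - flank_radius >= 1 &
    pos + flank_radius <= nchar(seqs[contig])
  if (any(!ok)) {
    warn(sprintf("%d variants dropped (non-SNV or flank out of bounds)",
                 sum(!ok)))
  }
  flank <- unname(substr(seqs[contig[ok]], pos[ok] - flank_radius,
                         pos[ok] + flank_radius))
  v <- variant_table(contig[ok], flank_radius + 1L, fx$REF[ok],
                     fx$ALT[ok], flank,
                     label = if (is.null(label)) NA_character_ else label[ok])
  v$pos <- pos[ok] # restore contig coordinates for reporting
  v
}

#' Write variant-call records as VCF
#'
#' Minimal VCF with QUAL in the QUAL column and MQ/QD/FS/DP as INFO
#' keys, the layout [read_called_variants()] expects.
#'
#' @param records Tibble with `contig`, `pos`, `ref`, `alt`, `QUAL`,
#'   `MQ`, `QD`, `FS`, `DP`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_called_variants <- function(records, path) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"RMS mapping quality\">",
    "##INFO=<ID=QD,Number=1,Type=Float,Description=\"Quality by depth\">",
    "##INFO=<ID=FS,Number=1,Type=Float,Description=\"Fisher strand phred score\">",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste0("##contig=<ID=", unique(records$contig), ">"),
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  body <- sprintf("%s\t%d\t.\t%s\t%s\t%s\t.\tMQ=%s;QD=%s;FS=%s;DP=%d",
                  records$contig, records$pos, records$ref, records$alt,
                  formatC(records$QUAL, format = "f", digits = 4),
                  formatC(records$MQ, format = "f", digits = 4),
                  formatC(records$QD, format = "f", digits = 4),
                  formatC(records$FS, format = "f", digits = 4),
                  as.integer(records$DP))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read variant-call records from VCF
#'
#' Reads CHROM/POS/REF/ALT, QUAL from the QUAL column, and MQ/QD/FS/DP
#' from INFO, into the tibble layout [hard_filter()] and
#' [count_edits()] consume. Absent INFO keys become `NA` (and fail the
#' filter with reason `missing:`).
#'
#' @param path VCF file.
#' @return A tibble with columns `contig`, `pos`, `ref`, `alt`,
#'   `QUAL`, `MQ`, `QD`, `FS`, `DP`.
#' @export
read_called_variants <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fx <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  num_info <- function(key) {
    suppressWarnings(as.numeric(vcfR::extract.info(vcf, key)))
  }
  tibble(contig = fx$CHROM, pos = as.integer(fx$POS),
         ref = fx$REF, alt = fx$ALT,
         QUAL = suppressWarnings(as.numeric(fx$QUAL)),
         MQ = num_info("MQ"), QD = num_info("QD"),
         FS = num_info("FS"), DP = num_info("DP"))
}
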