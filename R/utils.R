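## Small sequence utilities shared across modules. Sequences are plain
## uppercase character strings throughout; Biostrings is used at the I/O
## boundary only.

IUPAC_CHARS <- c("A", "C", "G", "T", "U", "R", "Y", "S", "W", "K", "M",
                 "B", "D", "H", "V", "N")

#' Reverse complement of DNA strings
#'
#' Vectorised reverse complement supporting the full IUPAC alphabet.
#'
#' @param x character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGTUacgtuRYSWKMBDHVryswkmbdhv",
                 "TGCAAtgcaaYRSWMKVHDByrswmkvhdb", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

## uppercase + whitespace strip
clean_seq <- function(x) toupper(gsub("[[:space:]]", "", x))

## stop early with a clear message unless all characters are IUPAC
assert_dna <- function(x, what = "sequence") {
  bad <- grepl(sprintf("[^%s-]", paste(IUPAC_CHARS, collapse = "")),
               toupper(x))
  if (any(bad))
    stop(what, " contains non-IUPAC characters", call. = FALSE)
  invisible(x)
}

## split a vector of sequences into a list of character vectors
seq_chars <- function(x) strsplit(toupper(x), "", fixed = TRUE)

## random DNA strings
random_dna <- function(n, length) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
          collapse = ""), character(1))
}

## Named character vector from a DNAStringSet or pass-through
as_seq_vector <- function(x) {
  if (inherits(x, "XStringSet")) {
    out <- as.character(x)
    names(out) <- names(x)
    return(out)
  }
  x
}

#' Read sequences from FASTA/FASTQ
#'
#' Thin wrappers around [Biostrings::readDNAStringSet()] returning named
#' character vectors, the package's working representation.
#'
#' @param path file path.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  as_seq_vector(Biostrings::readDNAStringSet(path, format = "fasta"))
}

#' @rdname read_fasta
#' @export
read_fastq <- function(path) {
  as_seq_vector(Biostrings::readDNAStringSet(path, format = "fastq"))
}

#' Write sequences to FASTA/FASTQ
#'
#' @param seqs named character vector of DNA sequences.
#' @param path output file path.
#' @param quality single quality character used to fill FASTQ qualities.
#' @return the path, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, path, format = "fasta")
  invisible(path)
}

#' @rdname write_fasta
#' @export
write_fastq <- function(seqs, path, quality = "I") {
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- names(seqs)
  q <- Biostrings::BStringSet(vapply(nchar(seqs), function(n)
    paste(rep(quality, n), collapse = ""), character(1)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q)
  invisible(path)
}

#' Bundled phorid COI reference barcode
#'
#' The COI barcode of a scuttle fly (Phoridae) voucher specimen, GenBank
#' accession MN403533, as a 657-nt fragment of the Folmer barcoding region.
#' It is translatable without stop codons in frame 1 under the invertebrate
#' mitochondrial code and carries the internal m1COlintF primer site 313 nt
#' upstream of its 3' end, which makes it a convenient template seed for
#' simulations and a worked-example input for the QC functions.
#'
#' @param pad_to_canonical pad the 5' end with one neutral base to the
#'   canonical 658-nt fragment length (the downstream reading frame is
#'   preserved); the padded position plays no role in translation-based
#'   checks.
#' @return a single named character string.
#' @export
coi_reference <- function(pad_to_canonical = FALSE) {
  path <- system.file("extdata", "phorid_coi_MN403533.fasta",
                      package = "nanobarcoder")
  x <- read_fasta(path)
  if (pad_to_canonical) {
    x[] <- paste0("A", x[])
    names(x) <- paste0(names(x), "_pad658")
  }
  x
}
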