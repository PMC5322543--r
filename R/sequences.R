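#' @importFrom stats median rnorm runif setNames
#' @importFrom utils read.table write.table
NULL

RNA_ALPHABET <- c("A", "C", "G", "U", "N")

.normalize_seq <- function(x, moltype) {
  x <- toupper(x)
  if (moltype == "rna") chartr("T", "U", x) else chartr("U", "T", x)
}

.check_alphabet <- function(seqs, ids, moltype) {
  pat <- if (moltype == "rna") "^[ACGUN]+$" else "^[ACGTN]+$"
  bad <- which(!grepl(pat, seqs))
  if (length(bad)) {
    stop(sprintf("illegal character in record %d (id '%s')", bad[1], ids[bad[1]]))
  }
  invisible(TRUE)
}

#' Read a FASTA file into a named sequence vector
#'
#' Sequences are stored uppercase in the declared molecule type: `T` and `U`
#' are interconverted so that all downstream scanning works on a single (RNA)
#' alphabet. Record order is preserved and duplicate identifiers are an
#' error.
#'
#' @param path path to a FASTA file (line wrapping allowed).
#' @param moltype `"rna"` or `"dna"`; the alphabet sequences are stored in.
#' @return named character vector of sequences with attribute `moltype`.
#' @export
read_fasta <- function(path, moltype = c("rna", "dna")) {
  moltype <- match.arg(moltype)
  if (!file.exists(path)) stop("file not found: ", path)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0) stop("no FASTA records in ", path)
  ids <- sub("\\s.*$", "", names(ss))
  if (any(ids == "")) stop("empty FASTA header in ", path)
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate id ", dup[1])
  seqs <- .normalize_seq(as.character(ss), moltype)
  if (any(nchar(seqs) == 0)) {
    stop("empty sequence for record '", ids[which(nchar(seqs) == 0)[1]], "'")
  }
  .check_alphabet(seqs, ids, moltype)
  names(seqs) <- ids
  attr(seqs, "moltype") <- moltype
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @param width line wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60) {
  stopifnot(!is.null(names(seqs)), all(nzchar(names(seqs))))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

#' Reverse complement of nucleotide sequences
#'
#' Antiparallel complement in the same molecule type; `N` complements to
#' itself. Applying the function twice returns the input.
#'
#' @param seqs character vector of sequences.
#' @param moltype `"rna"` or `"dna"`.
#' @return character vector of reverse complements.
#' @export
reverse_complement <- function(seqs, moltype = c("rna", "dna")) {
  moltype <- match.arg(moltype)
  seqs <- .normalize_seq(seqs, moltype)
  .check_alphabet(seqs, names(seqs) %||% as.character(seq_along(seqs)), moltype)
  set <- if (moltype == "rna") Biostrings::RNAStringSet(seqs) else Biostrings::DNAStringSet(seqs)
  out <- as.character(Biostrings::reverseComplement(set))
  names(out) <- names(seqs)
  out
}

#' Construct a mature miRNA record
#'
#' The family key groups sequence variants of the same miRNA: by default a
#' trailing `-3p`/`-5p` arm suffix and then a single trailing lowercase
#' variant letter are stripped from the identifier (`ath-miR842a-5p` ->
#' `ath-miR842`), so that divergence is counted at the level of named
#' miRNAs. Set `collapse_family = FALSE` to use the raw id.
#'
#' @param id miRNA identifier, e.g. `"ath-miR842a"`.
#' @param mature mature sequence (RNA; length 15-30).
#' @param age `"young"`, `"ancient"` or `"unknown"`.
#' @param family explicit family key, overriding the derived one.
#' @param collapse_family strip variant suffixes when deriving the family.
#' @return object of class `mirna` with fields `id`, `family`, `mature`, `age`.
#' @export
mirna <- function(id, mature, age = c("unknown", "young", "ancient"),
                  family = NULL, collapse_family = TRUE) {
  age <- match.arg(age)
  stopifnot(is.character(id), length(id) == 1, nzchar(id))
  mature <- .normalize_seq(mature, "rna")
  .check_alphabet(mature, id, "rna")
  L <- nchar(mature)
  if (L < 15 || L > 30) {
    stop("mature sequence of '", id, "' has length ", L, "; expected 15-30")
  }
  structure(
    list(id = id, family = family %||% mirna_family_key(id, collapse_family),
         mature = mature, age = age),
    class = "mirna"
  )
}

#' Derive a miRNA family key from an identifier
#'
#' @param id miRNA identifier.
#' @param collapse if `FALSE`, return `id` unchanged.
#' @return family key string.
#' @export
mirna_family_key <- function(id, collapse = TRUE) {
  if (!collapse) return(id)
  x <- sub("-[35]p$", "", id)
  sub("([0-9])[a-z]$", "\\1", x)
}

#' Construct a transcript record
#'
#' @param gene_id gene identifier.
#' @param seq nucleotide sequence (stored as RNA).
#' @param region annotation tag: `"cdna"`, `"cds"` or `"utr"`.
#' @return object of class `transcript`.
#' @export
transcript <- function(gene_id, seq, region = c("cdna", "cds", "utr")) {
  region <- match.arg(region)
  stopifnot(is.character(gene_id), length(gene_id) == 1, nzchar(gene_id))
  seq <- .normalize_seq(seq, "rna")
  .check_alphabet(seq, gene_id, "rna")
  structure(list(gene_id = gene_id, seq = seq, region = region),
            class = "transcript")
}

#' Build a list of miRNA records from a named sequence vector
#'
#' @param seqs named character vector (as from [read_fasta()]).
#' @param ages optional named vector of age classes, keyed by id.
#' @param collapse_family see [mirna()].
#' @return list of `mirna` objects, named by id.
#' @export
as_mirnas <- function(seqs, ages = NULL, collapse_family = TRUE) {
  out <- lapply(names(seqs), function(id) {
    age <- if (!is.null(ages) && id %in% names(ages)) ages[[id]] else "unknown"
    mirna(id, seqs[[id]], age = age, collapse_family = collapse_family)
  })
  names(out) <- names(seqs)
  out
}

#' Build a list of transcript records from a named sequence vector
#'
#' @param seqs named character vector (as from [read_fasta()]).
#' @param region annotation tag applied to all records.
#' @return list of `transcript` objects, named by gene id.
#' @export
as_transcripts <- function(seqs, region = "cdna") {
  out <- lapply(names(seqs), function(id) transcript(id, seqs[[id]], region))
  names(out) <- names(seqs)
  out
}
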